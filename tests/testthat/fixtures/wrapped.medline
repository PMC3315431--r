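PMID- 10001
TI  - Reactivation of latent tuberculosis in patients receiving tumour
      necrosis factor alpha blockers: a series of spontaneously reported
      cases with regulatory implications.
AB  - We describe twelve cases of tuberculosis reactivation reported after
      infliximab exposure. Screening before treatment is advised.

PMID- 10002
TI  - Cost-effectiveness of biologic therapy in rheumatoid arthritis.

PMID- 10003
TI  - New-onset psoriasis during etanercept therapy.
AB  - A case report of paradoxical psoriasis induction.
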