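# One multiword term per line; matched after stemming, joined with '_'.
tumor necrosis factor
adverse drug reaction
adverse event
serious adverse event
randomized controlled trial
rheumatoid arthritis
case report
clinical trial
side effect
crohn disease
risk assessment
drug safety
post marketing surveillance
opportunistic infection
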