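# Starter list of drug-class-agnostic (general) predictor terms.
# A user-supplied list in the same one-term-per-line format is accepted
# by read_general_terms(); multiword entries match detected phrases.
adverse
event
safety
case
report
trial
mortality
death
risk
reaction
toxicity
withdrawal
contraindication
warning
precaution
surveillance
pharmacovigilance
incidence
severe
serious
fatal
hospitalization
overdose
interaction
tolerability
harm
complication
onset
exposure
outcome
discontinuation
vigilance
monitoring
label
signal
causality
adverse event
adverse drug reaction
serious adverse event
case report
side effect
drug safety
risk assessment
post marketing surveillance
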