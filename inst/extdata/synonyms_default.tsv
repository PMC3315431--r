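# variant<TAB>canonical: British/American spelling variants and common
# pharmacology acronyms merged with their spelled-out forms.
tumour	tumor
anaemia	anemia
oedema	edema
haemorrhage	hemorrhage
diarrhoea	diarrhea
leukaemia	leukemia
paediatric	pediatric
oesophagus	esophagus
foetus	fetus
anaesthesia	anesthesia
behaviour	behavior
colour	color
favourable	favorable
licence	license
haematology	hematology
septicaemia	septicemia
hypersensitivity	allergy
adr	adverse drug reaction
ae	adverse event
sae	serious adverse event
rct	randomized controlled trial
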