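tool	damaging_min	neutral_max
ClinPred	0.5	0.25
DANNCoding	0.5	0.25
MetaSVM	0.5	0.25
REVEL	0.5	0.25
VEST4	0.5	0.25
FATHMM-XF	0.5	0.25
MetaLR	0.5	0.25
PhD-SNPg	0.5	0.25
LRT	0.5	0.25
MutationAssessor	0.5	0.25
MutationTaster	0.5	0.25
PROVEAN	0.5	0.25
PolyPhen-2	0.5	0.25
SIFT	0.5	0.25
CADD	0.5	0.25
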