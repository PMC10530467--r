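protein_a	protein_b	channel	score
F2	CRP	experimental	0.85
F2	CRP	database	0.8
F2	CRP	coexpression	0.6
F2	FGB	database	0.92
F2	FGB	experimental	0.7
F2	VWF	experimental	0.9
F2	VWF	database	0.85
F2	VWF	cooccurrence	0.3
PLAT	VWF	experimental	0.88
PLAT	VWF	database	0.8
FGB	THBS1	experimental	0.75
FGB	SERPINA1	database	0.72
FGB	VWF	experimental	0.6
FGB	VWF	coexpression	0.45
CRP	FGB	experimental	0.78
CRP	FGB	coexpression	0.55
F2	SERPINA1	experimental	0.82
CRP	VWF	database	0.74
CRP	IL1A	experimental	0.55
CRP	IL1A	coexpression	0.5
CRP	SERPINA1	coexpression	0.45
THBS1	VWF	experimental	0.5
F2	THBS1	database	0.42
CRP	THBS1	coexpression	0.3
FGB	IL1A	experimental	0.35
F2	PLAT	experimental	0.65
CRP	SAA1	experimental	0.6
FGB	FGA	neighborhood	0.9
FGB	FGA	fusion	0.3
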