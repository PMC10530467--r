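GO:0006953	GO-BP:acute-phase response	CRP	F2	SERPINA1	IL1A	SAA1	SAA2	HP	ORM1
KW-0011	keyword:Acute phase	CRP	F2	SERPINA1	IL1A	SAA1	SAA2
GOCC:0005577	GO-CC:fibrinogen complex	FGB	F2	CRP	THBS1	VWF	PLAT
GO:0008015	GO-BP:blood circulation	F5	F2	VWF	NOS3	EDN1	ACE	AGT	REN
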