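chrom	pos	ref	alt	gene	rsid	cdna_change	protein_change	consequence	maf_gnomad3	maf_1000g	clinvar	novel
chr1	159683091	T	C	CRP	rs1376711485	c.182T > C	p.Leu61Pro	missense	6.98295e-06	6.98295e-06	NR	FALSE
chr1	156869047	C	T	PEAR1	rs77795865	c.1142C > T	p.Ser381Phe	missense	0.0230726	0.0230726	NR	FALSE
chr1	165721011	C	T	TMCO1	rs78363884	c.486C > T	p.Leu162=	synonymous	0.033832	0.033832	B	FALSE
chr1	43349011	G	A	MPL	rs544064034	c.1242G > A	p.Ser414=	synonymous	6.98227e-06	6.98227e-06	LB	FALSE
chr1	245419111	C	T	KIF26B	rs201717788	c.507C > T	p.Val169=	synonymous	0.00295131	0.00295131	NR	FALSE
chr2	24940133	A	G	NCOA1	rs150066931	c.3995A > G	p.Asn1332Ser	missense	0.0015095	0.0015095	NR	FALSE
chr2	234637811	G	T	UGT1A3	rs146461519	c.736G > T	p.Val246Leu	missense	0.00043999	0.00043999	NR	FALSE
chr8	42039530	C	T	PLAT	rs2020921	c.490C > T	p.Arg164Trp	missense	0.012879	0.012879	NR	FALSE
chr9	5069022	C	G	JAK2	rs2230723	c.1177C > G	p.Leu393Val	missense	0.0134624	0.0134624	B	FALSE
chr11	46750921	C	A	F2	rs199772906	c.1542C > A	p.Asn514Lys	missense	0.000244325	0.000244325	NR	FALSE
chr11	18260033	A	C	SAA2	rs138605229	c.222A > C	p.Glu74Asp	missense	0.00552043	0.00552043	NR	FALSE
chr12	6128444	G	A	VWF	rs1800382	c.4196G > A	p.Arg1399His	missense	0.00895051	0.00895051	B;LB;LP;P	FALSE
chr14	58765013	C	T	ARID4A	rs146509016	c.8C > T	p.Ala3Val	missense	4.18819e-05	4.18819e-05	NR	FALSE
chr14	58838511	G	C	ARID4A	rs1051029502	c.2847G > C	p.Met949Ile	missense	6.97876e-06	6.97876e-06	NR	FALSE
chr14	94849022	C	T	SERPINA1	rs28931570	c.187C > T	p.Arg63Cys	missense	0.00151399	0.00151399	P;LP	FALSE
chr15	39886011	T	A	THBS1	.	c.2703T > A	p.Asp901Glu	missense	.	.	NR	TRUE
chr16	69745145	C	T	NQO1	rs1131341	c.415C > T	p.Arg139Trp	missense	0.0255606	0.0255606	NR	FALSE
chr16	81872011	T	C	PLCG2	rs138637229	c.1146T > C	p.Phe382=	synonymous	0.0071625	0.0071625	B;LB	FALSE
chr19	51561213	C	T	KLK13	rs34089525	c.325C > T	p.His109Tyr	missense	0.0217616	0.0217616	NR	FALSE
chr19	43255011	G	C	PSG8	.	c.26G > C	p.Cys9Ser	missense	.	.	NR	TRUE
chr20	48184011	C	T	PTGIS	rs61322884	c.531C > T	p.Tyr177=	synonymous	0.0221135	0.0221135	NR	FALSE
chr22	21131011	G	A	SERPIND1	rs35646566	c.423G > A	p.Leu141=	synonymous	0.0173203	0.0173203	NR	FALSE
chr4	155489011	G	A	FGB	rs4220	c.1433G > A	p.Arg478Lys	missense	0.22	0.2	NR	FALSE
chr2	113537011	G	T	IL1A	rs17561	c.340G > T	p.Ala114Ser	missense	0.3	0.28	NR	FALSE
chr1	169519049	A	G	F5	rs6027	c.5207T > C	p.Met1736Val	missense	0.25	0.24	NR	FALSE
chr1	201865011	G	A	LMOD1	rs2820312	c.1234G > A	p.Val412Ile	missense	0.3	0.29	NR	FALSE
chr3	186444011	C	G	KNG1	rs3733402	c.591C > G	p.Ile197Met	missense	0.35	0.33	NR	FALSE
chr19	43255241	G	A	PSG8	rs900000001	c.256G > A	p.Gly86Ser	missense	0.15	0.14	NR	FALSE
chr19	43255248	T	G	PSG8	rs900000002	c.263T > G	p.Ile88Arg	missense	0.12	0.11	NR	FALSE
chr15	39884911	A	G	THBS1	rs2292305	c.1567A > G	p.Thr523Ala	missense	0.21	0.2	NR	FALSE
chr15	39885442	A	G	THBS1	rs2228262	c.2099A > G	p.Asn700Ser	missense	0.09	0.085	NR	FALSE
chr14	94847011	G	A	SERPINA1	rs709932	c.374G > A	p.Arg125His	missense	0.24	0.23	NR	FALSE
chr14	94844111	A	C	SERPINA1	rs1303	c.1200A > C	p.Glu400Asp	missense	0.19	0.18	NR	FALSE
chr12	6125011	G	C	VWF	rs1800386	c.4414G > C	p.Asp1472His	missense	0.17	0.16	NR	FALSE
chr4	187192011	G	A	F11	rs900000003	c.901G > A	p.Ala301Thr	missense	0.002	0.002	NR	FALSE
chr2	179400011	C	T	TTN	rs900000004	c.10101C > T	p.Pro3367Leu	missense	0.0005	0.0005	NR	FALSE
chr17	45360011	C	T	ITGB3	rs900000005	c.500C > T	p.Thr167Ile	missense	0.003	0.003	NR	FALSE
chr1	169560011	C	T	SELP	rs900000006	c.700C > T	p.Arg234Cys	missense	0.01	0.1	NR	FALSE
chr2	128180011	G	A	PROC	rs900000007	c.565G > A	p.Val189Met	missense	0.002	0.002	NR	FALSE
chr6	6318011	A	G	F13A1	rs5985	c.103G > T	p.Val34Leu	missense	0.25	0.24	NR	FALSE
chr6	6318011	A	T	F13A1	rs5985	c.103G > A	p.Val34Met	missense	0.06	0.055	NR	FALSE
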