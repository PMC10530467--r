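rsid	gene	protein_change	region_features	splicing	eqtl	sqtl
rs146509016	ARID4A	p.Ala3Val	missense;splice_region	ESE_disruption	no data	no data
rs1051029502	ARID4A	p.Met949Ile	missense	ESE_disruption	no data	no data
rs199772906	F2	p.Asn514Lys	missense	ESE_disruption	no data	no data
rs2230723	JAK2	p.Leu393Val	missense	new_ESS;ESE_disruption;new_donor	no data	no data
rs34089525	KLK13	p.His109Tyr	missense	new_ESS	IGLON5	not found
rs544064034	MPL	p.Ser414=	synonymous;enhancer	none	no data	no data
rs150066931	NCOA1	p.Asn1332Ser	missense	ESE_disruption	no data	no data
rs1131341	NQO1	p.Arg139Trp	missense;splice_region;open_chromatin	donor_disruption	NOB1;COG4;PDXDC2P	NQO1;NOB1;NPIPB14P
rs77795865	PEAR1	p.Ser381Phe	missense	none	LRRC71	not found
rs2020921	PLAT	p.Arg164Trp	missense	new_ESE;new_donor	PLAT;POLB;AP3M2	SLC20A2;POLB
rs138605229	SAA2	p.Glu74Asp	missense	ESE_disruption	ns	not found
rs146461519	UGT1A3	p.Val246Leu	missense	new_donor	no data	no data
rs138637229	PLCG2	p.Phe382=	synonymous;CTCF_site	new_ESS	ns	not found
rs61322884	PTGIS	p.Tyr177=	synonymous	ESE_disruption	SLC9A8	not found
rs35646566	SERPIND1	p.Leu141=	synonymous;enhancer	ESE_disruption	AC000089.3	not found
rs78363884	TMCO1	p.Leu162=	synonymous	new_ESS	RP11-466F5.10	not found
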