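key	ClinPred	DANNCoding	MetaSVM	REVEL	VEST4	FATHMM-XF	MetaLR	PhD-SNPg	LRT	MutationAssessor	MutationTaster	PROVEAN	PolyPhen-2	SIFT	CADD
chr1:159683091:T:C	0.63	0.34	0.71	0.95	0.79	0.83	0.17	0.91	0.55	0.59	0.63	0.67	0.71	0.75	0.14
chr11:46750921:C:A	0.67	0.11	0.125	0.91	0.83	0.87	0.46	0.55	0.59	0.63	0.67	0.71	0.75	0.79	0.155
chr14:94849022:C:T	0.71	0.125	0.4	0.88	0.87	0.91	0.05	0.59	0.63	0.67	0.71	0.75	0.79	0.83	0.44
chr12:6128444:G:A	0.75	0.4	0.155	0.84	0.46	0.55	0.065	0.63	0.67	0.71	0.75	0.79	0.83	0.87	0.185
chr15:39886011:T:A	0.4	0.155	0.17	0.8	0.05	0.59	0.32	0.67	0.71	0.75	0.79	0.83	0.87	0.91	0.05
chr8:42039530:C:T	0.155	0.17	0.46	0.72	0.065	0.63	0.095	0.71	0.75	0.14	0.83	0.87	0.185	0.55	0.3
chr14:58765013:C:T	0.17	0.46	0.05	0.65	0.32	0.67	0.11	0.75	0.79	0.155	0.87	0.185	0.05	0.59	0.08
chr1:156869047:C:T	0.46	0.05	0.065	0.6	0.095	0.71	0.38	0.79	0.83	0.44	0.91	0.05	0.3	0.63	0.095
chr2:234637811:G:T	0.05	0.065	0.32	0.49	0.11	0.38	0.14	0.83	0.44	0.185	0.05	0.3	0.08	0.67	0.36
chr9:5069022:C:G	0.065	0.32	0.095	0.47	0.38	0.14	0.155	0.87	0.185	0.05	0.3	0.08	0.095	0.71	0.125
chr14:58838511:G:C	0.32	0.095	0.11	0.44	0.14	0.83	0.44	0.91	0.55	0.3	0.63	0.095	0.36	0.75	0.14
chr11:18260033:A:C	0.095	0.11	0.38	0.4	0.155	0.44	0.185	0.55	0.3	0.08	0.095	0.36	0.125	0.79	0.42
chr19:43255011:G:C	0.11	0.38	0.14	0.35	0.44	0.185	0.05	0.59	0.08	0.095	0.36	0.125	0.14	0.83	0.17
chr2:24940133:A:G	0.38	0.14	0.155	0.3	0.185	0.55	0.3	0.63	0.67	0.36	0.125	0.14	0.42	0.87	0.185
chr19:51561213:C:T	0.14	0.155	0.44	0.26	0.05	0.59	0.08	0.67	0.71	0.125	0.79	0.42	0.17	0.91	0.28
chr16:69745145:C:T	0.155	0.44	0.185	0.22	0.3	0.63	0.095	0.71	0.75	0.14	0.83	0.17	0.185	0.55	0.065
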