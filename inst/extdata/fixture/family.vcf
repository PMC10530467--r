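##fileformat=VCFv4.2
##source=famvarnet-fixture
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	I1	II1	II2	II3	III1	III2
chr1	159683091	rs1376711485	T	C	96.0	PASS	.	GT	0/1	0/0	0/1	0/1	0/1	0/1
chr1	156869047	rs77795865	C	T	92.0	PASS	.	GT	0/0	0/0	0/1	0/1	0/0	0/0
chr1	165721011	rs78363884	C	T	88.0	PASS	.	GT	0/0	0/0	0/1	0/0	0/0	0/0
chr1	43349011	rs544064034	G	A	91.0	PASS	.	GT	0/0	0/0	0/1	0/1	0/0	0/1
chr1	245419111	rs201717788	C	T	87.0	PASS	.	GT	0/0	0/1	0/0	0/0	0/1	0/1
chr2	24940133	rs150066931	A	G	94.0	PASS	.	GT	0/1	0/0	0/0	0/1	0/0	0/0
chr2	234637811	rs146461519	G	T	86.0	PASS	.	GT	0/0	0/0	0/0	0/1	0/0	0/0
chr8	42039530	rs2020921	C	T	97.0	PASS	.	GT	0/0	0/0	0/0	0/1	0/0	0/0
chr9	5069022	rs2230723	C	G	95.0	PASS	.	GT	0/1	0/0	0/1	0/1	0/0	0/1
chr11	46750921	rs199772906	C	A	98.0	PASS	.	GT	0/1	0/0	0/1	0/1	0/0	0/1
chr11	18260033	rs138605229	A	C	85.0	PASS	.	GT	0/0	0/1	0/0	0/0	0/1	0/1
chr12	6128444	rs1800382	G	A	99.0	PASS	.	GT	0/0	0/0	0/0	0/1	0/0	0/0
chr14	58765013	rs146509016	C	T	90.0	PASS	.	GT	0/0	0/1	0/0	0/0	0/1	0/1
chr14	58838511	rs1051029502	G	C	89.0	PASS	.	GT	0/1	0/0	0/0	0/1	0/0	0/0
chr14	94849022	rs28931570	C	T	96.0	PASS	.	GT	0/0	0/0	0/1	0/0	0/1	0/1
chr15	39886011	.	T	A	93.0	PASS	.	GT	0/1	0/0	0/1	0/0	0/0	0/1
chr16	69745145	rs1131341	C	T	92.0	PASS	.	GT	0/1	0/0	0/1	0/1	0/0	0/1
chr16	81872011	rs138637229	T	C	88.0	PASS	.	GT	0/0	0/0	0/1	0/0	0/0	0/0
chr19	51561213	rs34089525	C	T	91.0	PASS	.	GT	0/0	0/0	0/1	0/1	0/1	0/0
chr19	43255011	.	G	C	90.0	PASS	.	GT	0/1	0/0	0/1	0/1	0/1	0/1
chr20	48184011	rs61322884	C	T	87.0	PASS	.	GT	0/0	0/0	0/0	0/1	0/0	0/0
chr22	21131011	rs35646566	G	A	89.0	PASS	.	GT	0/1	0/0	0/0	0/1	0/0	0/0
chr4	155489011	rs4220	G	A	99.0	PASS	.	GT	0/1	0/0	0/1	0/1	0/0	0/1
chr2	113537011	rs17561	G	T	99.0	PASS	.	GT	0/1	0/0	0/1	0/0	0/0	1/1
chr1	169519049	rs6027	A	G	98.0	PASS	.	GT	0/0	0/0	0/1	0/1	0/0	0/1
chr1	201865011	rs2820312	G	A	97.0	PASS	.	GT	0/1	0/1	1/1	1/1	0/0	1/1
chr3	186444011	rs3733402	C	G	96.0	PASS	.	GT	0/0	0/1	0/0	0/0	0/0	0/1
chr19	43255241	rs900000001	G	A	95.0	PASS	.	GT	0/1	0/0	0/0	0/0	0/0	0/1
chr19	43255248	rs900000002	T	G	94.0	PASS	.	GT	0/0	0/0	0/0	0/0	0/0	0/1
chr15	39884911	rs2292305	A	G	93.0	PASS	.	GT	0/0	0/1	0/1	0/0	0/0	0/1
chr15	39885442	rs2228262	A	G	92.0	PASS	.	GT	0/0	0/1	0/1	0/0	0/0	0/1
chr14	94847011	rs709932	G	A	95.0	PASS	.	GT	0/0	0/0	0/1	0/0	0/1	0/1
chr14	94844111	rs1303	A	C	94.0	PASS	.	GT	0/0	0/0	0/1	0/0	0/1	0/1
chr12	6125011	rs1800386	G	C	96.0	PASS	.	GT	0/0	0/0	0/0	0/1	0/0	0/0
chr4	187192011	rs900000003	G	A	22.0	PASS	.	GT	0/0	0/0	0/0	0/1	0/0	0/0
chr2	179400011	rs900000004	C	T	99.0	PASS	.	GT	0/0	0/0	0/0	0/0	0/0	0/1
chr17	45360011	rs900000005	C	T	88.0	PASS	.	GT	0/0	0/1	0/0	0/0	0/1	0/0
chr1	169560011	rs900000006	C	T	90.0	PASS	.	GT	0/0	0/0	0/1	0/0	0/0	0/1
chr2	128180011	rs900000007	G	A	90.0	PASS	.	GT	0/0	0/1	0/0	1/1	0/0	0/0
chr6	6318011	rs5985	A	G,T	95.0	PASS	.	GT	1/2	0/1	0/2	0/0	0/0	0/1
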