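FAM1	I1	0	0	1	1
FAM1	II1	0	0	2	1
FAM1	II2	I1	0	1	2
FAM1	II3	I1	0	1	2
FAM1	III1	II2	II1	2	1
FAM1	III2	II2	II1	1	2
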