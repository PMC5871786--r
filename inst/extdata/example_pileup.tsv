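chrom	pos	ref	sample_id	nA	nC	nG	nT
chr1	1000	A	T_A	285	0	15	0
chr1	1000	A	T_B	148	0	152	0
chr1	1000	A	N_B	71	0	69	0
chr1	2000	C	T_A	0	292	0	8
chr1	2000	C	T_B	0	305	0	0
chr1	2000	C	N_B	0	143	0	0
chr1	3000	G	T_A	12	0	288	0
chr1	3000	G	T_B	31	0	269	0
chr1	3000	G	N_B	14	0	131	0
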