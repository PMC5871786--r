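chrom	pos	ref	alt	frequency
chr1	1000	A	G	0.30
chr1	3000	G	A	0.02
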