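sample_id	individual_id	pool_id	role	pool_fraction
T_A	A	lane1	tumour	0.25
N_A	A	lane1	normal	0.25
T_B	B	lane1	tumour	0.25
N_B	B	lane1	normal	0.25
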