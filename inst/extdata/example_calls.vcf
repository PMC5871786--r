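##fileformat=VCFv4.2
##source=synthetic example (constructed fixture, not real patient data)
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	T_A
chr1	1000	.	A	G	.	PASS	.	GT:AD:DP	0/1:285,15:300
chr1	2000	.	C	T	.	PASS	.	GT:AD:DP	0/1:292,8:300
chr1	3000	.	G	A	.	PASS	.	GT:AD:DP	0/1:288,12:300
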