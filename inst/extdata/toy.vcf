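##fileformat=VCFv4.2
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	S1	S2
chr9	100	.	A	T	.	.	.	GT:AD	0/1:3,7	1/1:0,12
chr9	250	.	AT	A	.	.	.	GT:AD	0/0:10,2	1/1:1,11
chr9	400	.	G	GCA	.	.	.	GT:AD	0/1:6,6	0/1:5,7
chr9	600	.	C	A,T	.	.	.	GT:AD	0/1:4,5,1	0/2:6,0,8
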