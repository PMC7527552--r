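##fileformat=VCFv4.2
##source=zanpop
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	acc1	acc2	acc3	acc4
locus000001	12	.	A	T	.	PASS	.	GT	0/1	0/0	1/1	./.
locus000001	87	.	C	G	.	PASS	.	GT	0/0	0/1	0/1	0/0
locus000002	33	.	G	A	.	PASS	.	GT	1/1	1/1	0/1	0/0
locus000003	5	.	T	C,A	.	PASS	.	GT	0/1	1/2	0/0	0/0
locus000004	61	.	A	G	.	PASS	.	GT	0/0	./.	0/1	1/1
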