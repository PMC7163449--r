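##fileformat=VCFv4.2
##INFO=<ID=AB,Number=1,Type=Integer,Description="Supporting reads">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO
chr1	22678	.	T	A	.	PASS	AB=7
chr1	46917	.	A	AGG	.	PASS	AB=4
chr1	8581	.	A	ACAGAG	.	PASS	AB=10
chr1	19229	.	T	G	.	PASS	AB=1
chr1	45231	.	GCT	G	.	PASS	AB=3
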