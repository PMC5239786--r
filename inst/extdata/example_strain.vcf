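##fileformat=VCFv4.2
##source=handmade-example
##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">
##FORMAT=<ID=AD,Number=R,Type=Integer,Description="Allelic depths">
##FORMAT=<ID=DP,Number=1,Type=Integer,Description="Read depth">
##FORMAT=<ID=BQ,Number=1,Type=Float,Description="Mean base quality">
#CHROM	POS	ID	REF	ALT	QUAL	FILTER	INFO	FORMAT	M1
chr1	100	.	G	A	40	PASS	.	GT:AD:DP:BQ	1/1:2,28:30:36
chr1	250	.	T	C	38	PASS	.	GT:AD:DP:BQ	0/1:15,12:27:34
chr1	300	.	G	GA	30	PASS	.	GT:AD:DP:BQ	0/1:18,10:28:33
chr1	410	.	AT	A	30	PASS	.	GT:AD:DP:BQ	0/1:16,11:27:32
chr1	500	.	C	T	35	PASS	.	GT:AD:DP:BQ	0/1:20,9:29:33
chr1	620	.	A	G	33	PASS	.	GT:AD:DP:BQ	1/1:0,31:31:35
chr1	700	.	G	A,T	25	PASS	.	GT:AD:DP:BQ	0/1:22,4,3:29:30
chr2	150	.	C	T	44	PASS	.	GT:AD:DP:BQ	1/1:1,25:26:37
chr2	260	.	T	A	41	PASS	.	GT:AD:DP:BQ	0/1:14,13:27:36
chr2	380	.	G	C	39	PASS	.	GT:AD:DP:BQ	1/1:0,22:22:38
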