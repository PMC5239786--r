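##gff-version 3
chr1	handmade	gene	1000	2000	.	+	.	ID=geneA
chr1	handmade	mRNA	1000	2000	.	+	.	ID=geneA.1;Parent=geneA
chr1	handmade	exon	1000	1399	.	+	.	Parent=geneA.1
chr1	handmade	exon	1600	2000	.	+	.	Parent=geneA.1
chr1	handmade	CDS	1100	1399	.	+	0	Parent=geneA.1
chr1	handmade	CDS	1600	1900	.	+	0	Parent=geneA.1
chr1	handmade	gene	5000	6000	.	-	.	ID=geneB
chr1	handmade	mRNA	5000	6000	.	-	.	ID=geneB.1;Parent=geneB
chr1	handmade	exon	5000	6000	.	-	.	Parent=geneB.1
chr1	handmade	CDS	5100	5900	.	-	0	Parent=geneB.1
chr2	handmade	gene	100	400	.	+	.	ID=geneC
chr2	handmade	mRNA	100	400	.	+	.	ID=geneC.1;Parent=geneC
chr2	handmade	exon	100	400	.	+	.	Parent=geneC.1
chr2	handmade	CDS	200	352	.	+	0	Parent=geneC.1
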