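chrom	pos	ref	A	C	G	T	qual
chr1	100	G	3	0	27	0	34
chr1	250	T	0	5	0	22	33
chr1	500	C	0	24	0	2	35
chr1	900	A	18	0	0	0	36
chr2	150	C	0	30	0	0	37
chr2	710	G	0	0	0	0	0
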