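gene	alias	pathway	protein_length	chrom	cds_anchor
BCL10	.	NF-kB canonical	233	chr1	85733001
BIRC3	API2	NF-kB canonical and non-canonical	604	chr11	102188001
CARD11	.	NF-kB canonical	1154	chr7	2946001
CD79A	.	NF-kB canonical	226	chr19	42381001
CD79B	.	NF-kB canonical	229	chr17	62006001
CYLD	.	NF-kB canonical and non-canonical	956	chr16	50775001
FAS	TNFRSF6	Extrinsic apoptosis	335	chr10	90750001
IKBKG	NEMO	NF-kB canonical	419	chrX	153770001
KMT2D	MLL2	Methylation	5537	chr12	49415001
MALT1	.	NF-kB canonical	824	chr18	56338001
MAP3K7	TAK1	NF-kB canonical	606	chr6	91223001
MAP3K14	NIK	NF-kB non-canonical	947	chr17	43340001
MYD88	.	NF-kB canonical	296	chr3	38181848
NFKBIA	.	NF-kB canonical	317	chr14	35870001
NOTCH1	.	Notch	2555	chr9	139383446
NOTCH2	.	Notch	2471	chr1	120454001
RIPK1	.	NF-kB canonical	671	chr6	3063001
RIPK2	.	NF-kB canonical	540	chr8	90769001
TNFAIP3	A20	NF-kB canonical	790	chr6	138188001
TNIP1	ABIN1	NF-kB canonical	636	chr5	150410001
TNIP2	ABIN2	NF-kB canonical	429	chr4	2743001
TP53	.	Extrinsic apoptosis	393	chr17	7572001
TRAF3	.	NF-kB non-canonical	568	chr14	103240001
TRAF6	.	NF-kB canonical	522	chr11	36510001
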