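gene	domain	aa_start	aa_end
NOTCH1	EGF	20	1426
NOTCH1	LNR	1449	1565
NOTCH1	HD-N	1571	1678
NOTCH1	HD-C	1686	1735
NOTCH1	TM	1736	1756
NOTCH1	RAM	1763	1850
NOTCH1	ANK	1927	2093
NOTCH1	TAD	2194	2398
NOTCH1	PEST	2428	2555
NOTCH2	EGF	26	1420
NOTCH2	LNR	1425	1541
NOTCH2	HD-N	1547	1650
NOTCH2	HD-C	1658	1705
NOTCH2	TM	1706	1726
NOTCH2	RAM	1736	1820
NOTCH2	ANK	1828	2002
NOTCH2	TAD	2110	2316
NOTCH2	PEST	2340	2471
KMT2D	PHD	147	440
KMT2D	HMG	471	560
KMT2D	NLS	1120	1160
KMT2D	FYRN	4707	4756
KMT2D	FYRC	5321	5366
KMT2D	SET	5397	5519
TNFAIP3	OTU	100	263
TNFAIP3	ZNF	392	777
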