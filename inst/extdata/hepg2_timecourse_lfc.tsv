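system	gene	lfc_d20	lfc_d30
2D	ABCB7	-2.86	-3.15
2D	ADAM2	-1.77	-1.88
2D	DDX11	-1.32	-2.04
2D	DDX52	-1.51	-2.39
2D	DIS3	-1.87	-2.09
2D	MYBBP1A	-2.95	-3.11
2D	POLR3C	-1.71	-2.38
2D	YARS2	-3.22	-3.75
2D	GOLGA8S	-2.58	-3.14
3D	CCDC63	-2.91	-3.15
3D	FDXACB1	-3.17	-3.51
3D	MYH7B	-3.10	-3.62
3D	NBPF9	-3.43	-3.73
3D	TAF6	-2.74	-3.80
3D	TLP1	-2.18	-3.25
2D	CYP2A13	1.21	1.31
2D	KMT2C	1.08	1.08
2D	OTOP3	1.21	1.53
2D	ZNF556	1.5	1.54
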