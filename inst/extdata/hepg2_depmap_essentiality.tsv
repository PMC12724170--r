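gene	gene_effect	essentiality
ABCB7	-1.90	Essential
ADAM2	0.001	Not essential
DDX11	-0.67	Essential
DDX52	-0.47	Essential
DIS3	-0.64	Essential
MYBBP1A	-0.46	Essential
POLR3C	-1.14	Essential
YARS2	-1.02	Essential
CCDC63	-0.21	Essential
FDXACB1	0.01	Not essential
TAF6	-1.65	Essential
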