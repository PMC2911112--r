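spot_id	gene	protein_ratio	mrna_ratio
3214	Uchl1	0.58	0.63
662	Dppa4	0.65	0.75
3549	Igf2bp2	0.65	1.39
2836	Sipa1l1	0.74	1.54
425	Lap3	0.76	0.72
2512	Hspd1	0.78	0.75
3410	Eif1a	0.8	0.76
403	Pkm2	1.26	3.05
935	Bdh1	1.31	1.53
645	Serpinh1	1.44	1.36
2920	Ldhb	1.46	0.64
3562	Cotl1	1.62	1.39
3653	S100a11	1.89	1.18
3144	Sept1	2.28	0.71
1134	Gsto1	2.77	3.73
3588	Fabp3	3.05	2.2
3078	Apoe	3.28	0.8
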