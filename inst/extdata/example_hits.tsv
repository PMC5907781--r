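locus_0	AY123456.1	97.6	70	2	0	1	70	101	170	3.1e-28	130.1	6183
locus_1	MN777777.1	99.2	70	1	0	1	70	12	81	1.2e-31	138.0	8521
locus_2	KX555555.1	92.3	65	5	0	1	65	40	104	5.0e-20	101.4	6183
locus_2	JQ444444.1	88.1	65	8	0	1	65	7	71	2.2e-16	88.9	6239
locus_3	LC333333.1	85.0	60	9	0	1	60	90	149	8.8e-13	75.0	6239
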