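# Published benchmark deviation statistics (kcal/mol) of standard and
# dispersion-corrected DFT interaction energies of (H2O)n clusters against
# quantum Monte Carlo references; input for the statistics-layer worked
# examples (MAE per molecule = MAE / n_monomers with 2-decimal display
# rounding). variant: dft = uncorrected, d4 = default correction,
# d4opt = refitted scaling factors.
model	variant	n_monomers	err	mse	mae
BLYP	dft	9	19.7	405.77	19.7
BLYP	d4	9	1.33	4.65	1.72
B3LYP	dft	9	9.71	99.4	9.71
B3LYP	d4	9	-4.02	17.21	4.02
PBE	dft	9	0.7	2.42	1.27
PBE	d4	9	-8.39	72.84	8.39
PBE0	dft	9	-1.21	4.07	1.56
PBE0	d4	9	-9.2	89.66	9.2
BLYP	dft	15	43.58	2044.31	43.58
BLYP	d4	15	3.329	26.95	3.82
B3LYP	dft	15	23.08	581.8	23.08
B3LYP	d4	15	-7.19	54.89	7.19
PBE	dft	15	5.05	34.93	5.08
PBE	d4	15	-15.13	233.15	15.13
PBE0	dft	15	0.28	3.61	1.45
PBE0	d4	15	-17.59	325.94	17.59
BLYP	dft	27	79.1	6503.64	79.1
BLYP	d4	27	1.24	23.58	3.69
B3LYP	dft	27	42.92	1936.93	42.92
B3LYP	d4	27	-16.7	286.26	16.7
PBE	dft	27	11.38	165.4	11.41
PBE	d4	27	-28.93	845.73	28.93
PBE0	dft	27	4.29	30.44	4.76
PBE0	d4	27	-31.9	1035.2	31.9
PBE	d4opt	9	-1.8	5.06	1.9
B3LYP	d4opt	9	-0.75	2.03	1.14
revPBE	d4opt	9	1.31	3.32	1.55
revPBE0	d4opt	9	0.60	1.99	1.16
PBE	d4opt	15	-0.40	5.69	2.02
B3LYP	d4opt	15	-0.03	8.35	2.42
revPBE	d4opt	15	0.92	7.2	2.26
revPBE0	d4opt	15	-0.09	6.16	1.97
PBE	d4opt	27	0.57	24.12	3.97
B3LYP	d4opt	27	-2.8	23.92	4.12
revPBE	d4opt	27	0.75	8.31	2.14
revPBE0	d4opt	27	-0.83	7.89	1.9
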