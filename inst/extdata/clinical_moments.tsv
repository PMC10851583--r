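variable	type	hlap_mean	hlap_sd	bap_mean	bap_sd	hlap_n	bap_n
age	truncnorm	39.71	9.86	58.3	15.95	na	na
hospital_stay	truncnorm	10.47	7.31	10.43	4.64	na	na
bmi	truncnorm	27.76	3.72	25.11	4.32	na	na
wbc	truncnorm	14.14	4.18	11.69	3.84	na	na
crp	lognormal	185.08	115.24	61.66	64.39	na	na
bun	truncnorm	5.76	9.17	4.73	1.84	na	na
creatinine	truncnorm	70.04	27.18	68.36	13.34	na	na
calcium	truncnorm	2.06	0.23	2.09	0.22	na	na
glucose	truncnorm	10.68	5.20	7.38	2.70	na	na
tg	lognormal	18.00	19.30	0.91	0.34	na	na
tc	lognormal	9.20	5.27	4.02	0.90	na	na
male	flag	na	na	na	na	128	11
diabetes	flag	na	na	na	na	87	4
hypertension	flag	na	na	na	na	36	12
fatty_liver	flag	na	na	na	na	138	7
ards	flag	na	na	na	na	10	2
sap	flag	na	na	na	na	10	2
msap_sap	flag	na	na	na	na	83	5
ctsi_gt4	flag	na	na	na	na	72	5
recurrence	flag	na	na	na	na	91	7
repeated_recurrence	flag	na	na	na	na	61	3
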