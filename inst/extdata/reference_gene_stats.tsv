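comparison	gene	meanA	meanB	scale	fc	fr
LOAD_vs_HC	MRPL51	703.3	472.4	raw	0.57	1.29
LOAD_vs_HC	CETN2	867.0	683.0	raw	0.34	1.19
LOAD_vs_HC	LOC401206	18073.7	12083.0	raw	0.58	1.17
LOAD_vs_HC	RPL36AL	7168.5	4527.8	raw	0.66	1.16
LOAD_vs_HC	LOC646200	3563.2	1760.4	raw	1.02	1.09
LOAD_vs_HC	RPS25	18110.8	11732.2	raw	0.63	1.04
LOAD_vs_HC	RPA3	450.8	332.4	raw	0.44	0.99
LOAD_vs_HC	RPS27A	17344.8	13010.2	raw	0.41	0.96
LOAD_vs_HC	LOC653658	1550.3	823.9	raw	0.91	0.93
LOAD_vs_HC	LOC648000	2445.1	1119.2	raw	1.13	0.92
LOAD_vs_HC	LOC650276	5630.2	2744.5	raw	1.04	0.90
LOAD_vs_HC	MRPL33	401.1	328.1	raw	0.29	0.88
LOAD_vs_HC	RPL17	3505.5	1567.4	raw	1.16	0.87
LOAD_vs_HC	CALML4	542.0	411.4	raw	0.40	0.87
LOAD_vs_HC	RPL36AL	2909.1	1789.1	raw	0.70	0.86
LOAD_vs_HC	TOMM7	3249.9	1607.3	raw	1.02	0.85
LOAD_vs_HC	PSMC2	815.7	610.1	raw	0.42	0.84
LOAD_vs_HC	COX17	1047.2	713.6	raw	0.55	0.83
LOAD_vs_HC	SNRPB2	869.3	649.1	raw	0.42	0.83
LOAD_vs_HC	RPL6	14487.9	11020.4	raw	0.39	0.82
LOAD_vs_HC	LOC731365	4091.6	2900.3	raw	0.50	0.81
LOAD_vs_HC	ATP5J2	1179.6	961.4	raw	0.30	0.80
LOAD_vs_HC	LOC646483	4230.1	2885.7	raw	0.55	0.80
LOAD_vs_HC_fisher	HSP90AA1	2538.09	1641.60	raw	0.63	NA
LOAD_vs_HC_fisher	RAB37	862.35	1065.21	raw	-0.30	NA
LOAD_vs_HC_fisher	TMSB10	11572.19	9995.74	raw	0.21	NA
LOAD_vs_HC_fisher	TROVE2	312.54	351.15	raw	-0.17	NA
LOAD_vs_HC_rf	LOC401206	14.08	13.48	log2	0.06	NA
LOAD_vs_HC_rf	MRPL51	9.41	8.84	log2	0.09	NA
LOAD_vs_HC_rf	SNTB2	9.35	9.63	log2	-0.04	NA
MCI_vs_HC	TAX1BP1	1300.3	833.5	raw	0.64	NA
MCI_vs_HC	RPS4Y1	1388.9	1567.6	raw	-0.17	NA
MCI_vs_HC	RPL17	3505.5	1222.9	raw	1.52	NA
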