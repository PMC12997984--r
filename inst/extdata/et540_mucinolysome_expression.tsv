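gene_id	gene_name	mucinolysome	tpm_mucin	tpm_glucose	log2fc	padj
CGICJO_04010	cSca5	Yes	29423.84	20802.21	0.75	4.26E-08
CGICJO_01195	cSca2	Yes	4901.69	631.74	3.22	7.88E-43
CGICJO_03730	cGH33.e1	Yes	2682.69	623.14	2.36	2.80E-30
CGICJO_01190	cSca1	Yes	2463.29	1187.68	1.31	7.24E-13
CGICJO_03740	cGH84.e2	Yes	2450.03	428.50	2.77	1.71E-54
CGICJO_04735	cSca4	Yes	2391.40	1390.71	1.03	1.48E-21
CGICJO_03735	GH2	No	2294.58	421.43	2.7	3.62E-55
CGICJO_04135	cGH29.e1	Yes	1553.41	563.54	1.72	3.78E-19
CGICJO_02795	GH112	No	1392.12	1269.76	0.39	7.89E-03
CGICJO_06705	cGH101.e1	Yes	1305.38	635.12	1.30	1.62E-08
CGICJO_03725	cGH101.e3	Yes	1170.98	402.92	1.79	4.14E-26
CGICJO_09790	cGH20.e4	Yes	1125.86	485.76	1.47	3.95E-11
CGICJO_08830	cGH2.e1	Yes	1123.93	300.89	2.16	7.61E-25
CGICJO_09785	cGH20.e3	Yes	737.38	314.30	1.49	1.24E-12
CGICJO_11990	cGH136.e3	Yes	626.21	59.90	3.65	4.80E-71
CGICJO_11995	GH136	No	557.68	48.74	3.78	2.82E-74
CGICJO_08435	cGH84.e1	Yes	362.00	530.18	-0.30	0.016
CGICJO_08900	cGH111.e1	Yes	359.99	318.36	0.43	0.003
CGICJO_03845	GH84	No	339.17	102.61	1.98	1.96E-29
CGICJO_02305	cSca3	Yes	326.07	37.52	3.37	9.31E-203
CGICJO_08430	cGH136.e1	Yes	312.95	188.02	0.99	1.80E-12
CGICJO_11985	cGH136.e2	Yes	293.16	54.27	2.69	8.90E-63
CGICJO_03840	cGH89.e1	Yes	171.60	42.38	2.28	5.31E-32
CGICJO_05460	cP5	Yes	167.63	264.65	-0.41	9.86E-04
CGICJO_04790	cP3	Yes	116.88	162.26	-0.22	0.05
CGICJO_11355	cP1	Yes	111.94	70.45	0.92	7.79E-12
CGICJO_10190	cGH101.e4	Yes	102.19	7.28	4.08	6.73E-54
CGICJO_08925	cGH20.e2/cP4	Yes	95.11	21.99	2.38	2.03E-05
CGICJO_10215	GH36	No	61.36	23.04	1.67	2.18E-16
CGICJO_05315	cGH95.e1	Yes	60.52	8.40	3.11	3.66E-41
CGICJO_05805	cGH51.e1	Yes	55.09	59.69	0.14	0.48
CGICJO_06105	GH36	No	49.78	51.93	0.19	0.11
CGICJO_04835	GH42	No	47.60	58.79	-0.05	0.67
CGICJO_03095	cGH20.e1	Yes	45.12	32.84	0.72	0.002
CGICJO_03090	cP2	Yes	44.44	36.39	0.55	0.036
CGICJO_02140	GH31	No	31.02	29.66	0.32	0.026
CGICJO_00480	cGH101.e2	Yes	13.13	2.13	2.87	5.14E-48
CGICJO_08465	cP6	Yes	11.96	68.91	-2.28	2.43E-69
CGICJO_07620	cGH43.e1	Yes	3.56	7.50	-0.82	4.24E-04
CGICJO_10290	GH36	No	2.33	2.19	0.34	0.33
CGICJO_10285	GH36	No	1.24	1.14	0.36	0.45
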