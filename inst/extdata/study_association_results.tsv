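variant_id	gene	variant	study	n_cases	n_controls	case_freq_pct	control_freq_pct	or	ci_low	ci_high	p
1:22923859	EPHA8	p.Pro607His	FHCRC	1265	1230	2.50	0.94	2.70	1.20	6.07	0.017
1:22923859	EPHA8	p.Pro607His	PLCO	4222	2899	1.82	1.86	0.97	0.69	1.39	0.876
2:242695399	D2HGDH	p.Ala225Thr	FHCRC	1265	1230	2.46	1.06	2.37	1.23	4.56	0.010
2:242695399	D2HGDH	p.Ala225Thr	PLCO	4222	2899	1.46	1.87	0.80	0.55	1.16	0.228
3:97868404	OR5H14	p.Met59Val	FHCRC	1265	1230	2.54	1.39	1.85	1.02	3.36	0.042
3:97868404	OR5H14	p.Met59Val	PLCO	4222	2899	2.42	1.93	1.27	0.92	1.78	0.157
6:32946119	BRD2	p.Ala605Pro	FHCRC	1265	1230	0.79	0.16	4.99	1.09	22.86	0.038
6:32946119	BRD2	p.Ala605Pro	PLCO	4222	2899	0.62	0.73	0.87	0.49	1.57	0.640
17:46805705	HOXB13	p.Gly84Glu	FHCRC	1265	1230	1.42	0.25	5.68	1.67	19.36	0.005
17:46805705	HOXB13	p.Gly84Glu	PLCO	4222	2899	1.11	0.31	3.78	1.94	8.28	0.0003
17:48542714	CHAD	p.Ala342Asp	FHCRC	1265	1230	1.43	0.41	3.51	1.30	9.49	0.013
17:48542714	CHAD	p.Ala342Asp	PLCO	4222	2899	1.23	0.97	1.28	0.81	2.06	0.292
19:11486354	SWSAP1	p.Leu118Ile	FHCRC	1265	1230	2.55	0.98	2.61	1.34	5.09	0.005
19:11486354	SWSAP1	p.Leu118Ile	PLCO	4222	2899	1.44	1.31	1.12	0.75	1.70	0.593
22:20024596	TANGO2	p.Ser17Ter	FHCRC	1265	1230	2.77	1.47	1.93	1.08	3.42	0.026
22:20024596	TANGO2	p.Ser17Ter	PLCO	4222	2899	2.30	1.66	1.39	0.98	1.99	0.065
22:50873415	PPP6R2	p.Arg103His	FHCRC	1265	1230	2.07	1.06	2.02	1.03	3.96	0.040
22:50873415	PPP6R2	p.Arg103His	PLCO	4222	2899	1.83	1.66	1.09	0.76	1.58	0.636
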