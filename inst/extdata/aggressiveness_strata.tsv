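variant_id	gene	stratum	noncarrier	carrier	freq_pct	or	ci_low	ci_high	p
17:46805705	HOXB13	control	4110	12	0.29	1.00	NA	NA	NA
17:46805705	HOXB13	non-aggressive	4347	47	1.07	3.80	2.02	7.17	3.62e-5
17:46805705	HOXB13	aggressive	1074	18	1.65	5.54	2.71	11.32	2.68e-6
22:20024596	TANGO2	control	4059	66	1.60	1.00	NA	NA	NA
22:20024596	TANGO2	non-aggressive	4298	97	2.21	1.37	1.00	1.89	0.047
22:20024596	TANGO2	aggressive	1055	35	3.21	2.06	1.35	3.13	0.00075
3:97868404	OR5H14	control	4051	73	1.77	1.00	NA	NA	NA
3:97868404	OR5H14	non-aggressive	4278	111	2.53	1.43	1.06	1.93	0.019
3:97868404	OR5H14	aggressive	1066	23	2.11	1.23	0.77	1.99	0.387
17:48542714	CHAD	control	4087	33	0.80	1.00	NA	NA	NA
17:48542714	CHAD	non-aggressive	4336	56	1.28	1.54	1.00	2.38	0.049
17:48542714	CHAD	aggressive	1076	14	1.28	1.65	0.89	3.08	0.112
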