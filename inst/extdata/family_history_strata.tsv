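variant_id	gene	family_history	case_noncarrier	case_carrier	case_freq_pct	control_noncarrier	control_carrier	control_freq_pct	or	ci_low	ci_high	p
17:46805705	HOXB13	no	4596	49	1.05	3697	11	0.30	3.61	1.87	6.97	0.00013
17:46805705	HOXB13	yes	733	13	1.74	340	1	0.29	NA	NA	NA	0.032
22:20024596	TANGO2	no	4531	114	2.45	3655	56	1.51	1.65	1.19	2.28	0.0025
22:20024596	TANGO2	yes	728	17	2.28	333	8	2.35	0.96	0.41	2.28	0.928
3:97868404	OR5H14	no	4526	113	2.44	3645	65	1.75	1.39	1.02	1.90	0.036
3:97868404	OR5H14	yes	724	20	2.69	335	6	1.76	1.47	0.57	3.82	0.427
17:48542714	CHAD	no	4582	59	1.27	3675	31	0.84	1.48	0.95	2.30	0.080
17:48542714	CHAD	yes	737	9	1.21	339	2	0.59	NA	NA	NA	0.183
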