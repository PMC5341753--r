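category	n_cases	pct_cases	n_controls	pct_controls	or	ci_low	ci_high	p
0	5087	92.98	3928	95.60	1.00	NA	NA	NA
1	367	6.71	178	4.33	1.58	1.31	1.91	1.0e-7
2-3	17	0.31	3	0.07	4.25	1.20	14.97	0.024
>=1	384	7.02	181	4.40	1.63	1.36	1.95	1.4e-7
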