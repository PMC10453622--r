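mutant_id	rel_activity_pct	topt_C	t_half_min	fold_increase_reported	thermo_score_reported	activity_score_reported	composite_score_reported
WT	100	55	23.14	1.00	100	100	10000.00
N18L	72.30	60	46.63	2.02	201.51	72.3	14570.10
N18Q	0.23	NA	NA	NA	NA	NA	NA
S97A	90.89	55	41.25	1.78	178.26	90.89	16202.84
S97H	98.52	55	26.16	1.13	113.47	98.52	11178.42
G98R	19.95	55	230.71	9.97	997.02	19.95	19892.83
G98E	6.19	55	731.39	31.61	316.07	6.19	19552.51
G98Q	3.45	NA	NA	NA	NA	NA	NA
S99L	96.66	60	38.37	1.66	165.82	96.66	16027.04
S99A	111.01	60	32.40	1.40	140.02	111.01	15543.38
G100K	0.15	NA	NA	NA	NA	NA	NA
G100E	7.88	60	548.80	23.72	237.17	7.88	18691.55
G100A	93.82	55	47.92	2.07	207.09	93.82	19429.07
S101I	3.26	NA	NA	NA	NA	NA	NA
S101G	90.29	55	28.18	1.22	121.79	94.23	10996.84
S101V	12.69	65	190.44	8.23	822.99	12.69	10445.30
E110L	31.28	60	36.94	1.60	159.64	31.28	4993.94
E110R	0.12	NA	NA	NA	NA	NA	NA
R143F	0.02	NA	NA	NA	NA	NA	NA
R143L	75.73	60	62.96	2.72	272.07	75.73	20604.41
R143G	98.24	60	28.14	1.65	164.83	98.24	16192.72
R143V	78.53	55	49.81	2.15	215.25	78.53	16903.36
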