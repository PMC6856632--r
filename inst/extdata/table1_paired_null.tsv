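sample	JB01	R02	R04	R08	R09	R14	R18	R19	JB02	JB03	JB04	JB05	R17
JB01	NA	1.00	1.00	1.00	1.00	1.00	1.00	0.99	1.00	1.00	1.00	1.00	0.45
R02	-0.61	NA	1.00	1.00	1.00	1.00	1.00	1.00	1.00	1.00	1.00	1.00	0.97
R04	0.65	0.49	NA	1.00	1.00	1.00	1.00	1.00	1.00	1.00	1.00	1.00	0.99
R08	-0.44	1.20	0.18	NA	1.00	1.00	1.00	1.00	1.00	1.00	1.00	1.00	0.95
R09	-1.29	-0.26	-1.24	-0.43	NA	1.00	1.00	0.99	0.67	0.97	1.00	1.00	0.86
R14	0.69	-0.51	-1.16	-0.48	-0.87	NA	1.00	1.00	1.00	1.00	1.00	1.00	0.81
R18	0.17	0.22	0.65	0.10	0.10	0.02	NA	1.00	1.00	1.00	0.97	0.99	0.45
R19	-1.32	-0.75	-1.34	-1.10	0.76	1.03	-0.67	NA	0.73	1.00	1.00	1.00	0.72
JB02	2.45	-0.04	-0.89	-0.39	0.88	0.95	1.35	-0.70	NA	-0.17	0.16	0.98	-0.04
JB03	0.67	-0.61	0.07	-0.32	-1.06	-0.02	0.19	-1.94	-1.40	NA	0.63	1.00	0.64
JB04	-0.24	-0.13	-1.05	-0.33	-0.64	1.49	1.15	-1.99	-0.96	-0.34	NA	0.82	-0.93
JB05	-0.60	-0.41	-1.03	-0.01	-0.85	-1.06	-0.60	-1.26	-0.75	-0.65	-0.07	NA	0.46
R17	0.00	0.71	-1.58	-0.47	-1.18	0.22	1.37	-2.13	0.01	-1.40	-1.44	-1.30	NA
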