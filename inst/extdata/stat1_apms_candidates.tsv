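gene_name	pSTAT1_vs_GFP_log2	pSTAT1_vs_GFP_sd	pSTAT1_vs_GFP_p	STAT1_vs_GFP_log2	STAT1_vs_GFP_sd	STAT1_vs_GFP_p	pSTAT1_vs_STAT1_log2	pSTAT1_vs_STAT1_sd	pSTAT1_vs_STAT1_p	known_from_literature
CHCHD3	-1.78	1.17	5.9e-02	1.32	0.22	4.4e-03	-4.35	1.20	2.4e-02	No
ETFB	-1.48	0.58	2.3e-02	2.45	0.12	4.1e-04	-4.33	1.01	1.8e-02	No
NDUFS3	-2.16	0.84	2.3e-02	1.29	0.10	1.0e-03	-3.82	1.02	2.3e-02	No
UBE2M	-0.06	0.13	2.4e-01	1.93	0.33	4.9e-03	-3.53	0.54	7.7e-03	No
UCHL1	-0.86	0.48	4.5e-02	2.27	0.37	4.3e-03	-3.48	1.10	3.2e-02	No
PFKL	0.26	0.45	2.1e-01	1.82	0.26	3.5e-03	-2.44	0.26	3.7e-03	No
PGD	-0.18	0.72	3.3e-01	1.18	0.13	1.8e-04	-1.20	0.97	9.1e-02	No
ERP44	-0.49	0.43	5.3e-02	1.58	0.47	3.4e-03	-1.10	0.99	1.1e-01	No
CANX	-0.40	0.45	8.6e-02	1.70	0.53	3.9e-03	-1.09	1.26	1.8e-01	No
PYGL	-0.02	0.29	4.5e-01	1.26	0.33	2.4e-03	-0.97	0.79	9.0e-02	No
UQCRC1	0.29	0.30	4.6e-02	1.30	0.45	1.5e-03	-0.68	0.70	9.4e-02	No
GLO1	0.96	0.83	5.1e-02	2.29	0.20	9.5e-05	-0.66	1.00	2.8e-01	No
HSD17B4	-0.06	0.39	4.1e-01	1.54	0.36	1.7e-03	-0.44	0.72	4.0e-01	No
FARSB	-0.24	0.49	2.0e-01	1.11	0.25	1.5e-03	-0.37	0.83	4.4e-01	No
STAT2	3.35	0.38	2.0e-04	3.23	0.55	6.5e-04	-0.24	0.65	5.2e-01	Yes
ACTG1	1.08	0.61	3.6e-03	0.34	0.24	1.6e-02	0.42	0.86	3.4e-01	No
TBCA	1.25	0.76	1.0e-02	1.36	0.54	2.4e-03	0.72	1.08	2.1e-01	No
SPTAN1	1.22	0.25	1.1e-03	0.37	0.36	6.6e-02	0.75	0.48	5.1e-02	Yes
STAT1	5.61	0.53	8.1e-07	4.47	0.75	1.4e-05	0.97	1.02	6.9e-02	Yes
LDHB	1.06	0.30	1.7e-04	-0.16	0.47	2.2e-01	1.09	0.89	3.0e-02	Yes
STMN1	1.45	0.19	3.0e-03	-0.39	0.70	1.7e-01	1.26	1.26	1.4e-01	No
PABPC3	1.28	0.18	3.3e-03	-0.59	0.43	7.2e-02	1.43	0.29	1.3e-02	No
CAPRIN1	1.13	0.28	4.1e-04	-0.32	0.24	2.2e-02	1.55	0.58	4.0e-03	No
PTBP2	1.16	0.06	3.8e-04	-0.63	0.02	1.3e-04	1.71	0.07	6.1e-04	No
DES	2.11	0.61	3.1e-03	-0.30	0.48	1.5e-01	2.25	0.73	8.6e-03	No
PLEC	1.74	0.24	3.1e-03	-1.23	0.89	7.0e-02	2.86	0.71	2.0e-02	Yes
INA	3.28	0.52	4.1e-03	-0.32	0.49	1.9e-01	2.97	0.17	1.1e-03	No
KPNA6	1.99	0.26	2.9e-03	-1.50	0.13	1.3e-03	3.18	0.51	8.3e-03	Yes
KPNA1	3.90	0.31	1.0e-03	-1.06	0.29	1.2e-02	3.67	0.58	1.1e-03	Yes
STAT3	3.45	0.05	3.9e-05	-2.67	0.31	2.2e-03	5.28	0.40	1.9e-03	Yes
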