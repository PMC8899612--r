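genome	region	hp_count	phage_count	me_count	functional_count	orf_total	ssv_count	length_bp	from_bp	to_bp	hp_pct_printed	hp_dens_printed	phage_pct_printed	phage_dens_printed	me_pct_printed	me_dens_printed	functional_pct_printed	functional_dens_printed	ssv_dens_printed
MI1A	scrapyard	175	9	22	38	244	231	193839	32354	226193	71.7	9.03	3.69	0.46	9.02	1.13	15.6	1.96	11.9
MI1I	scrapyard	175	10	21	43	249	162	193534	32354	225888	70.3	9.04	4.02	0.52	8.43	1.09	17.3	2.22	8.37
MI1III	scrapyard	162	9	16	41	228	NA	184321	32348	216669	71.1	8.79	3.95	0.49	7.02	0.87	18.0	2.22	NA
S2.4	scrapyard	95	1	7	51	154	3	134793	31234	166027	61.7	7.05	0.65	0.07	4.55	0.52	33.1	3.78	0.22
OL2a6	scrapyard	142	0	32	41	215	61	156636	293058	449694	66.1	9.07	0	0	14.9	2.04	19.1	2.62	3.89
S2.4alt	scrapyard	150	18	12	61	241	278	188208	456809	645017	62.2	7.97	7.47	0.96	4.98	0.64	25.3	3.24	14.8
MI1A	outside	1026	13	116	1592	2747	452	2555267	NA	NA	37.4	4.02	0.47	0.05	4.22	0.45	58.0	6.23	1.77
MI1I	outside	1040	12	127	1588	2767	413	2560898	NA	NA	37.6	4.06	0.43	0.05	4.59	0.50	57.4	6.20	1.61
MI1III	outside	1027	12	118	1590	2747	NA	2564129	NA	NA	37.4	4.01	0.44	0.05	4.30	0.46	57.9	6.20	NA
S2.4	outside	853	12	49	1522	2497	317	2350931	NA	NA	34.2	3.63	0.48	0.05	1.96	0.21	61.0	6.47	1.35
OL2a6	outside	1030	8	169	1576	2783	355	2538403	NA	NA	37.0	4.06	0.29	0.03	6.07	0.67	56.6	6.21	1.40
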