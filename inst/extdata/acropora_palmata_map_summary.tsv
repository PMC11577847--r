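chromosome	length_mb	n_markers	male_cm	female_cm	avg_cm	male_rate	female_rate	avg_rate
Chr1	27.05	318	54.05	148.29	100.3	2	5.48	3.71
Chr2	25.92	171	40.18	109.24	74.4	1.55	4.21	2.87
Chr3	21.9	155	42.18	116.88	79.18	1.93	5.34	3.62
Chr4	20.87	162	39.21	106.44	72.52	1.88	5.1	3.47
Chr5	20.54	162	36.65	95.01	65.39	1.78	4.63	3.18
Chr6	19.02	141	30.51	82.65	56.32	1.6	4.35	2.96
Chr7	18.66	143	30.61	102.66	66.01	1.64	5.5	3.54
Chr8	18.59	134	52.66	124.59	88.27	2.83	6.7	4.75
Chr9	17.67	129	47.71	96.2	71.22	2.7	5.44	4.03
Chr10	16.55	142	27.67	92.01	59.61	1.67	5.56	3.6
Chr11	16.42	113	51.94	115.02	81.74	3.16	7	4.98
Chr12	14.67	150	59.69	97.83	77.91	4.07	6.67	5.31
Chr13	14.61	112	28.92	79.95	53.63	1.98	5.47	3.67
Chr14	13.63	82	41.22	93.92	66.93	3.02	6.89	4.91
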