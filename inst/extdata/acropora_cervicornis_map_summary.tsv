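chromosome	length_mb	n_markers	male_cm	female_cm	avg_cm	male_rate	female_rate	avg_rate
LG1	30.19	442	73.09	121.41	97.25	2.42	4.02	3.22
LG2	26.77	495	50.62	96.61	73.61	1.89	3.61	2.75
LG3	25.26	356	46.01	90.6	68.3	1.82	3.59	2.7
LG4	20.97	433	54.48	89.59	72.03	2.6	4.27	3.44
LG5	20.93	562	53.8	108.28	81.04	2.57	5.17	3.87
LG6	20.56	340	27.42	76.07	51.75	1.33	3.7	2.52
LG7	20.05	305	33.67	87.65	60.66	1.68	4.37	3.03
LG8	18.96	310	44.65	94.95	69.8	2.36	5.01	3.68
LG9	18.53	340	48.51	78.94	63.73	2.62	4.26	3.44
LG10	18.31	256	39.53	88.94	64.24	2.16	4.86	3.51
LG11	17.26	170	19.07	61.6	40.34	1.1	3.57	2.34
LG12	15.82	231	43.29	81.06	62.17	2.74	5.12	3.93
LG13	15.29	277	20.43	71.73	46.08	1.34	4.69	3.01
LG14	14.96	342	47.38	105.34	76.36	3.17	7.04	5.1
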