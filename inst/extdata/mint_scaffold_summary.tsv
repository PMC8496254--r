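type	name	size_mbp	pct_genome	n_targeted	n_retained
Scaffold	S01	62.45	11.64	464	168
Scaffold	S02	51.27	9.56	430	141
Scaffold	S03	51.75	9.65	491	194
Scaffold	S04	49.09	9.15	510	211
Scaffold	S05	46.64	8.70	459	174
Scaffold	S06	44.69	8.33	323	137
Scaffold	S07	44.57	8.31	375	149
Scaffold	S08	38.13	7.11	335	133
Scaffold	S09	37.15	6.93	328	125
Scaffold	S10	40.48	7.55	428	194
Scaffold	S11	31.60	5.89	381	139
Scaffold	S12	30.25	5.64	322	130
Contig	X1059	0.02	0.004	1	0
Contig	X1121	0.01	0.003	1	0
Contig	X1124	0.01	0.003	1	0
Contig	X1181	0.01	0.001	1	1
Contig	X233	0.12	0.023	1	0
Contig	X321	0.45	0.084	1	0
Contig	X368	0.05	0.009	1	0
Contig	X394_1	1.35	0.251	22	18
Contig	X394_2	0.94	0.175	6	4
Contig	X394_3	0.12	0.023	2	1
Contig	X713	0.01	0.001	1	0
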