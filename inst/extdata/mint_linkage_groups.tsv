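linkage_group	n_markers	n_from_other_scaffold	n_from_contig	density_cM	length_cM	largest_gap_cM	n_gaps_gt10	n_distorted	pct_distorted
LG01	168	3	0	0.52	87.65	4.78	0	168	100.00
LG02	165	1	23	0.54	89.48	25.53	1	3	1.82
LG03	191	0	0	0.33	63.96	3.34	0	2	1.05
LG04	210	0	0	0.37	77.20	2.54	0	0	0.00
LG05	176	2	0	0.38	66.11	4.97	0	92	52.27
LG06	140	4	0	0.88	122.61	15.00	2	11	7.86
LG07	146	0	0	0.58	84.09	13.83	1	78	53.42
LG08	133	0	0	0.44	58.26	5.32	0	1	0.75
LG09	125	0	1	0.45	56.32	3.67	0	1	0.80
LG10	195	1	0	0.48	92.64	23.67	1	5	2.56
LG11	140	1	0	0.41	57.72	2.74	0	2	1.43
LG12	130	0	0	0.66	86.14	13.56	2	2	1.54
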