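# Published confusion counts and printed precision/recall/F1 (percent) for
# predictions against a 317-edge ground-truth network over 30 yeast
# cell-cycle genes (undirected matching).
method	tp	fp	fn	precision	recall	f1
raw_ppin	165	95	152	63.46	52.05	57.19
extended_ppin_subnet	229	220	88	51.00	72.24	59.79
extended_ppin_global	240	260	77	48.00	75.71	58.75
clr	190	312	127	37.85	59.94	46.40
genie3	128	202	189	38.79	40.38	39.57
tigress	140	207	177	40.35	44.16	42.17
gmm	172	266	145	39.27	54.26	45.56
ghmm	258	329	59	43.95	81.39	57.08
r_scores_ghmm	250	262	67	48.83	78.86	60.31
bgm_r_scores	202	237	115	46.01	63.72	53.44
bgm	139	201	178	40.88	43.85	42.31
bgm_gmm	185	293	132	38.70	58.36	46.54
bgm_c_scores	170	150	147	53.13	53.63	53.38
nariai_ghmm	176	273	141	39.20	55.52	45.95
imoto_ghmm	184	293	133	38.57	58.04	46.35
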