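stage	locus_key	range_label	center	n
birth	SLA-1(*12:01)	0	0	10
birth	SLA-1(*12:01)	0.01-0.099	0.05	0
birth	SLA-1(*12:01)	0.1-0.199	0.15	133
birth	SLA-1(*12:01)	0.2-0.299	0.25	52
birth	SLA-1(*12:01)	0.3-0.399	0.35	56
birth	SLA-1(*12:01)	0.4-0.499	0.45	55
birth	SLA-1(*12:01)	0.5-0.599	0.55	115
birth	SLA-1(*12:01)	0.6-0.699	0.65	116
birth	SLA-1(*12:01)	0.7-0.799	0.75	48
birth	SLA-1(*12:01)	0.8-0.899	0.85	56
birth	SLA-1(*12:01)	0.9-0.999	0.95	9
birth	SLA-1(*13:01)	0	0	10
birth	SLA-1(*13:01)	0.01-0.099	0.05	24
birth	SLA-1(*13:01)	0.1-0.199	0.15	109
birth	SLA-1(*13:01)	0.2-0.299	0.25	74
birth	SLA-1(*13:01)	0.3-0.399	0.35	31
birth	SLA-1(*13:01)	0.4-0.499	0.45	87
birth	SLA-1(*13:01)	0.5-0.599	0.55	96
birth	SLA-1(*13:01)	0.6-0.699	0.65	47
birth	SLA-1(*13:01)	0.7-0.799	0.75	112
birth	SLA-1(*13:01)	0.8-0.899	0.85	36
birth	SLA-1(*13:01)	0.9-0.999	0.95	24
birth	SLA-3	0	0	10
birth	SLA-3	0.01-0.099	0.05	29
birth	SLA-3	0.1-0.199	0.15	149
birth	SLA-3	0.2-0.299	0.25	144
birth	SLA-3	0.3-0.399	0.35	156
birth	SLA-3	0.4-0.499	0.45	48
birth	SLA-3	0.5-0.599	0.55	50
birth	SLA-3	0.6-0.699	0.65	47
birth	SLA-3	0.7-0.799	0.75	17
birth	SLA-2	0	0	10
birth	SLA-2	0.01-0.099	0.05	0
birth	SLA-2	0.1-0.199	0.15	44
birth	SLA-2	0.2-0.299	0.25	141
birth	SLA-2	0.3-0.399	0.35	19
birth	SLA-2	0.4-0.499	0.45	43
birth	SLA-2	0.5-0.599	0.55	36
birth	SLA-2	0.6-0.699	0.65	141
birth	SLA-2	0.7-0.799	0.75	119
birth	SLA-2	0.8-0.899	0.85	56
birth	SLA-2	0.9-0.999	0.95	35
birth	SLA-2	1.0-1.099	1.05	6
birth	DRB1	0	0	6
birth	DRB1	0.01-0.199	0.10	124
birth	DRB1	0.2-0.299	0.25	86
birth	DRB1	0.3-0.399	0.35	126
birth	DRB1	0.4-0.499	0.45	69
birth	DRB1	0.5-0.599	0.55	146
birth	DRB1	0.6-0.699	0.65	67
birth	DRB1	0.7-0.799	0.75	20
birth	DRB1	0.8-0.899	0.85	6
birth	DQB1	0	0	18
birth	DQB1	0.001-0.049	0.025	107
birth	DQB1	0.05-0.099	0.075	109
birth	DQB1	0.10-0.149	0.125	138
birth	DQB1	0.15-0.199	0.175	112
birth	DQB1	0.20-0.249	0.225	118
birth	DQB1	0.25-0.299	0.275	33
birth	DQB1	0.30-0.349	0.325	15
weaning	SLA-1(*12:01)	0	0	9
weaning	SLA-1(*12:01)	0.01-0.099	0.05	0
weaning	SLA-1(*12:01)	0.1-0.199	0.15	124
weaning	SLA-1(*12:01)	0.2-0.299	0.25	48
weaning	SLA-1(*12:01)	0.3-0.399	0.35	54
weaning	SLA-1(*12:01)	0.4-0.499	0.45	52
weaning	SLA-1(*12:01)	0.5-0.599	0.55	109
weaning	SLA-1(*12:01)	0.6-0.699	0.65	110
weaning	SLA-1(*12:01)	0.7-0.799	0.75	48
weaning	SLA-1(*12:01)	0.8-0.899	0.85	54
weaning	SLA-1(*12:01)	0.9-0.999	0.95	9
weaning	SLA-1(*13:01)	0	0	9
weaning	SLA-1(*13:01)	0.01-0.099	0.05	21
weaning	SLA-1(*13:01)	0.1-0.199	0.15	103
weaning	SLA-1(*13:01)	0.2-0.299	0.25	68
weaning	SLA-1(*13:01)	0.3-0.399	0.35	30
weaning	SLA-1(*13:01)	0.4-0.499	0.45	84
weaning	SLA-1(*13:01)	0.5-0.599	0.55	91
weaning	SLA-1(*13:01)	0.6-0.699	0.65	46
weaning	SLA-1(*13:01)	0.7-0.799	0.75	107
weaning	SLA-1(*13:01)	0.8-0.899	0.85	35
weaning	SLA-1(*13:01)	0.9-0.999	0.95	23
weaning	SLA-3	0	0	9
weaning	SLA-3	0.01-0.099	0.05	24
weaning	SLA-3	0.1-0.199	0.15	141
weaning	SLA-3	0.2-0.299	0.25	135
weaning	SLA-3	0.3-0.399	0.35	149
weaning	SLA-3	0.4-0.499	0.45	48
weaning	SLA-3	0.5-0.599	0.55	49
weaning	SLA-3	0.6-0.699	0.65	45
weaning	SLA-3	0.7-0.799	0.75	17
weaning	SLA-2	0	0	9
weaning	SLA-2	0.01-0.099	0.05	0
weaning	SLA-2	0.1-0.199	0.15	39
weaning	SLA-2	0.2-0.299	0.25	133
weaning	SLA-2	0.3-0.399	0.35	19
weaning	SLA-2	0.4-0.499	0.45	43
weaning	SLA-2	0.5-0.599	0.55	34
weaning	SLA-2	0.6-0.699	0.65	132
weaning	SLA-2	0.7-0.799	0.75	114
weaning	SLA-2	0.8-0.899	0.85	55
weaning	SLA-2	0.9-0.999	0.95	33
weaning	SLA-2	1.0-1.099	1.05	6
weaning	DRB1	0	0	5
weaning	DRB1	0.01-0.199	0.10	117
weaning	DRB1	0.2-0.299	0.25	83
weaning	DRB1	0.3-0.399	0.35	120
weaning	DRB1	0.4-0.499	0.45	67
weaning	DRB1	0.5-0.599	0.55	135
weaning	DRB1	0.6-0.699	0.65	67
weaning	DRB1	0.7-0.799	0.75	18
weaning	DRB1	0.8-0.899	0.85	5
weaning	DQB1	0	0	17
weaning	DQB1	0.001-0.049	0.025	102
weaning	DQB1	0.05-0.099	0.075	101
weaning	DQB1	0.10-0.149	0.125	132
weaning	DQB1	0.15-0.199	0.175	110
weaning	DQB1	0.20-0.249	0.225	109
weaning	DQB1	0.25-0.299	0.275	31
weaning	DQB1	0.30-0.349	0.325	15
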