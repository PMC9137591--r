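taxon	bw_group	JC	JM	CC	mean_bw_printed
Actinobacteria	LBW	2.54	1.55	0.38	1.49
Actinobacteria	HBW	4.40	0.46	0.17	1.67
Bacteroidetes	LBW	0.38	20.83	45.25	22.15
Bacteroidetes	HBW	1.18	39.99	51.61	30.93
Cyanobacteria	LBW	4.82	0.47	0.05	1.78
Cyanobacteria	HBW	3.76	1.47	0.06	1.76
Deinococcus Thermus	LBW	0.04	0.02	0.00	0.02
Deinococcus Thermus	HBW	0.02	0.00	0.00	0.01
Epsilonbacteraeota	LBW	0.00	0.00	0.00	0.00
Epsilonbacteraeota	HBW	0.01	0.11	0.00	0.04
Firmicutes	LBW	88.16	74.76	51.77	71.57
Firmicutes	HBW	76.67	54.78	46.92	59.46
Patescibacteria	LBW	0.25	0.05	0.00	0.10
Patescibacteria	HBW	4.03	0.12	0.00	1.38
Proteobacteria	LBW	3.78	2.25	2.39	2.81
Proteobacteria	HBW	9.88	2.72	0.98	4.53
Tenericutes	LBW	0.01	0.08	0.15	0.08
Tenericutes	HBW	0.05	0.34	0.25	0.21
B/F Ratio	LBW	0.00	0.32	0.89	0.40
B/F Ratio	HBW	0.02	0.76	1.13	0.64
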