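taxon	JC	JM	CC
Actinobacteria	3.47	1.00	0.28
Bacteroidetes	0.78	30.41	48.43
Cyanobacteria	4.29	0.97	0.06
Deinococcus Thermus	0.03	0.01	0.00
Epsilonbacteraeota	0.01	0.06	0.00
Firmicutes	82.42	64.77	49.35
Patescibacteria	2.14	0.09	0.00
Proteobacteria	6.83	2.48	1.68
Tenericutes	0.03	0.21	0.20
B/F Ratio	0.01	0.54	1.01
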