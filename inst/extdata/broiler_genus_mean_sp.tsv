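taxon	JC	JM	CC
Alistipes	0.01	1.17	1.65
Bacteroides	0.43	26.67	44.33
Enterococcus	0.123	0.025	0.002
Ruminococcaceae UCG-010	0.00	0.17	0.24
Ruminococcaceae UCG-013	0.010	0.078	0.285
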