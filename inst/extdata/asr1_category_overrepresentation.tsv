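category	k	p_value	pct_sample	pct_genome	fold
Cellulose synthase	4	1.38e-05	2.45	0.08	31.0
Beta 1,3-glucano hydrolases	3	5.40e-03	1.84	0.12	15.3
Pectin esterases	3	7.57e-03	1.84	0.18	10.2
Breaking down	4	9.84e-03	2.45	0.12	20.2
Membrane Intrinsic Proteins	5	2.78e-06	3.07	0.02	135.7
Miscellaneous	23	1.07e-05	14.11	0.18	78.4
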