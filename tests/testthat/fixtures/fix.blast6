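fix_phage	fix_genome	100.000	1200	0	0	1	1200	3001	4200	0.0	2217
fix_phage	fix_genome	100.000	1200	0	0	1	1200	7400	6201	0.0	2217
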