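layer	type	n	pct_genome	pct_transcripts	mean_size_mb	se_size_mb
all	deletion	46	17.59	19.70	7.24	0.92
all	insertion	5	0.88	0.95	3.13	2.78
L1	deletion	769	88.88	92.20	7.71	0.22
L1	insertion	23	5.64	5.30	4.11	1.23
L23	deletion	467	76.90	82.60	7.28	0.29
L23	insertion	10	2.48	2.50	3.75	1.97
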