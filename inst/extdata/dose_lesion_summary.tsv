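dose_gy	n_samples	del_per_sample	del_total	del_mean_size_mb	ins_per_sample	ins_total	ins_mean_size_mb	all_per_sample	all_total
15	16	2.62	42	6.54	0	0	0.00	2.62	42
30	28	4.57	128	6.29	0.14	4	0.16	4.71	132
45	214	5.46	1168	6.42	0.20	43	0.58	5.66	1211
60	3	5.33	16	7.25	1.67	5	2.97	7.00	21
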