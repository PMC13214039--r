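individual	dose_gy	scaffold	start	end	size_mb	type	leaf_dosage	root_dosage	layer
P011	45	Chr03_B	31500001	32857933	1.36	deletion	0.70	1.08	L1
P011	45	Chr03_E	17100001	18400000	1.30	deletion	0.38	0.09	L2/3
P011	45	Chr04_A	33500001	34843660	1.34	deletion	0.66	0.97	L1
P011	45	Chr04_K	1	7000001	7.00	deletion	0.68	1.00	L1
P011	45	Chr05_F	6600001	7700000	1.10	deletion	0.37	0.09	L2/3
P011	45	Chr07_B	900001	3200000	2.30	deletion	0.80	0.99	L1
P011	45	Chr08_A	1	13500000	13.50	deletion	0.68	1.04	L1
P011	45	Chr11_D	1	2500000	2.50	deletion	0.73	1.03	L1
P011	45	Chr12_F	1	5900000	5.90	deletion	0.70	1.09	L1
P028	45	Chr02_A	26700001	27400000	0.70	deletion	0.73	1.01	L1
P028	45	Chr06_C	1	10200000	10.20	deletion	0.71	0.97	L1
P028	45	Chr08_A	18800001	19800000	1.00	deletion	0.35	0.14	L2/3
P028	45	Chr11_D	1	7000000	7.00	deletion	0.74	1.06	L1
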