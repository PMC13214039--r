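sample	compound	abundance_pct
BM_2019	menthol	42
BM_2019	menthyl_acetate	4.5
BM_2019	neomenthol	3.47
BM_2019	menthone	19.7
P11	menthol	2.6
P11	menthyl_acetate	0.54
P11	neomenthol	22.5
P11	menthone	41.8
BM_2020	menthol	42
BM_2020	menthyl_acetate	9.5
BM_2020	menthone	12.8
BM_2020	neomenthol	4.68
BM_2020	isomenthone	1.74
P28	menthol	4
P28	menthyl_acetate	0.89
P28	menthone	46.5
P28	neomenthol	17
P28	isomenthone	3.1
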