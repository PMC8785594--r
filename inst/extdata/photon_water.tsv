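energy_MeV	mu_cm2_g	muen_cm2_g
0.1	0.1707	0.02546
0.15	0.1505	0.02764
0.2	0.137	0.02967
0.3	0.1186	0.03192
0.4	0.1061	0.03279
0.5	0.09687	0.03299
0.6	0.08956	0.03284
0.8	0.07865	0.03206
1	0.07072	0.03103
1.25	0.06323	0.02965
1.5	0.05754	0.02833
2	0.04942	0.02608
3	0.03969	0.02281
3.5	0.0364	0.02161
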