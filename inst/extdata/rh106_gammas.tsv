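energy_MeV	intensity_per_decay
0.428180	0.000145
0.511855	0.204000
0.616220	0.007330
0.621930	0.099300
0.873490	0.004390
1.050410	0.015600
1.128020	0.004040
1.198510	0.000170
1.562250	0.001630
1.766260	0.003360
1.988420	0.002870
2.112400	0.000410
2.242100	0.000660
2.406880	0.000630
3.036300	0.000140
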