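depth_mm	value
 0.05	2.018383415
 0.10	1.978759543
 0.15	1.940822942
 0.20	1.904337654
 0.25	1.868992955
 0.30	1.834562279
 0.35	1.800868362
 0.40	1.767818928
 0.45	1.735395858
 0.50	1.703576321
 0.55	1.672383466
 0.60	1.641817241
 0.65	1.611906538
 0.70	1.582655074
 0.75	1.554078577
 0.80	1.526193364
 0.85	1.498981725
 0.90	1.472439207
 0.95	1.446538575
 1.00	1.421249208
 1.05	1.396523247
 1.10	1.372299845
 1.15	1.348529278
 1.20	1.325157023
 1.25	1.302155090
 1.30	1.279505444
 1.35	1.257206340
 1.40	1.235263456
 1.45	1.213683193
 1.50	1.192473247
 1.55	1.171638819
 1.60	1.151180820
 1.65	1.131099267
 1.70	1.111383916
 1.75	1.092026748
 1.80	1.073011660
 1.85	1.054318620
 1.90	1.035931738
 1.95	1.017830297
 2.00	1.000000000
 2.05	0.982431174
 2.10	0.965116735
 2.15	0.948058889
 2.20	0.931257127
 2.25	0.914714375
 2.30	0.898433035
 2.35	0.882410616
 2.40	0.866648688
 2.45	0.851141979
 2.50	0.835882398
 2.55	0.820863833
 2.60	0.806076967
 2.65	0.791514598
 2.70	0.777167340
 2.75	0.763031363
 2.80	0.749100243
 2.85	0.735374194
 2.90	0.721850958
 2.95	0.708531318
 3.00	0.695415828
 3.05	0.682502360
 3.10	0.669790416
 3.15	0.657277581
 3.20	0.644959067
 3.25	0.632831409
 3.30	0.620889963
 3.35	0.609129444
 3.40	0.597546253
 3.45	0.586137119
 3.50	0.574898592
 3.55	0.563829870
 3.60	0.552930331
 3.65	0.542198568
 3.70	0.531633888
 3.75	0.521236031
 3.80	0.511002176
 3.85	0.500930448
 3.90	0.491019079
 3.95	0.481263700
 4.00	0.471661661
 4.05	0.462210129
 4.10	0.452906790
 4.15	0.443748980
 4.20	0.434735191
 4.25	0.425864566
 4.30	0.417135780
 4.35	0.408548015
 4.40	0.400100040
 4.45	0.391790902
 4.50	0.383618853
 4.55	0.375581803
 4.60	0.367677108
 4.65	0.359903635
 4.70	0.352258797
 4.75	0.344740022
 4.80	0.337346061
 4.85	0.330074865
 4.90	0.322926261
 4.95	0.315898477
 5.00	0.308990865
 5.05	0.302201630
 5.10	0.295529873
 5.15	0.288974583
 5.20	0.282533279
 5.25	0.276205192
 5.30	0.269988177
 5.35	0.263879957
 5.40	0.257879032
 5.45	0.251984252
 5.50	0.246194167
 5.55	0.240507132
 5.60	0.234922242
 5.65	0.229438551
 5.70	0.224055050
 5.75	0.218770680
 5.80	0.213584198
 5.85	0.208494311
 5.90	0.203499657
 5.95	0.198598639
 6.00	0.193789792
 6.05	0.189071668
 6.10	0.184442910
 6.15	0.179902319
 6.20	0.175448702
 6.25	0.171081083
 6.30	0.166798480
 6.35	0.162600085
 6.40	0.158484724
 6.45	0.154451385
 6.50	0.150498957
 6.55	0.146626134
 6.60	0.142831608
 6.65	0.139113950
 6.70	0.135471838
 6.75	0.131904021
 6.80	0.128409129
 6.85	0.124986216
 6.90	0.121634192
 6.95	0.118352186
 7.00	0.115139323
 7.05	0.111994898
 7.10	0.108917932
 7.15	0.105907692
 7.20	0.102963147
 7.25	0.100083356
 7.30	0.097267147
 7.35	0.094513420
 7.40	0.091821003
 7.45	0.089188870
 7.50	0.086615783
 7.55	0.084100875
 7.60	0.081643115
 7.65	0.079241605
 7.70	0.076895545
 7.75	0.074604192
 7.80	0.072366728
 7.85	0.070182346
 7.90	0.068050182
 7.95	0.065969325
 8.00	0.063938768
 8.05	0.061957465
 8.10	0.060024328
 8.15	0.058138302
 8.20	0.056298327
 8.25	0.054503420
 8.30	0.052752661
 8.35	0.051045253
 8.40	0.049380509
 8.45	0.047757852
 8.50	0.046176695
 8.55	0.044636635
 8.60	0.043137168
 8.65	0.041677810
 8.70	0.040257990
 8.75	0.038877051
 8.80	0.037534197
 8.85	0.036228550
 8.90	0.034959088
 8.95	0.033724735
 9.00	0.032524309
 9.05	0.031356662
 9.10	0.030220615
 9.15	0.029115073
 9.20	0.028039011
 9.25	0.026991568
 9.30	0.025971995
 9.35	0.024979725
 9.40	0.024014315
 9.45	0.023075489
 9.50	0.022163036
 9.55	0.021276842
 9.60	0.020416790
 9.65	0.019582765
 9.70	0.018774573
 9.75	0.017991965
 9.80	0.017234543
 9.85	0.016501818
 9.90	0.015793146
 9.95	0.015107772
10.00	0.014444793
10.05	0.013803231
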