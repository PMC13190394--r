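country,direction,statistic,p_value
Austria,CO2->MIGR,1.049,0.306
Belgium,CO2->MIGR,1.362,0.506
France,CO2->MIGR,5.623,0.060
Germany,CO2->MIGR,0.135,0.935
Italy,CO2->MIGR,15.020,0.002
Luxembourg,CO2->MIGR,0.129,0.720
Czechia,CO2->MIGR,0.320,0.572
Estonia,CO2->MIGR,5.219,0.022
Finland,CO2->MIGR,0.001,0.972
Hungary,CO2->MIGR,0.523,0.470
Lithuania,CO2->MIGR,8.832,0.032
Malta,CO2->MIGR,0.945,0.815
Portugal,CO2->MIGR,0.191,0.662
Slovak Republic,CO2->MIGR,8.981,0.030
Sweden,CO2->MIGR,10.991,0.012
Slovenia,CO2->MIGR,3.758,0.289
Spain,CO2->MIGR,3.373,0.338
Latvia,CO2->MIGR,8.525,0.036
Ireland,CO2->MIGR,5.214,0.157
Greece,CO2->MIGR,7.295,0.063
Denmark,CO2->MIGR,0.411,0.814
Croatia,CO2->MIGR,0.723,0.868
Bulgaria,CO2->MIGR,1.603,0.449
Netherlands,CO2->MIGR,3.916,0.141
Cyprus,CO2->MIGR,4.045,0.132
Poland,CO2->MIGR,0.510,0.917
Romania,CO2->MIGR,19.058,0.000
Austria,MIGR->CO2,0.006,0.941
Belgium,MIGR->CO2,2.259,0.323
France,MIGR->CO2,0.234,0.890
Germany,MIGR->CO2,3.545,0.170
Italy,MIGR->CO2,10.035,0.018
Luxembourg,MIGR->CO2,0.952,0.329
Czechia,MIGR->CO2,0.012,0.912
Estonia,MIGR->CO2,0.157,0.692
Finland,MIGR->CO2,1.928,0.165
Hungary,MIGR->CO2,3.512,0.061
Lithuania,MIGR->CO2,3.877,0.275
Malta,MIGR->CO2,16.399,0.001
Portugal,MIGR->CO2,1.978,0.160
Slovak Republic,MIGR->CO2,2.882,0.410
Sweden,MIGR->CO2,1.790,0.617
Slovenia,MIGR->CO2,4.095,0.251
Spain,MIGR->CO2,5.210,0.157
Latvia,MIGR->CO2,1.297,0.730
Ireland,MIGR->CO2,4.480,0.214
Greece,MIGR->CO2,2.984,0.394
Denmark,MIGR->CO2,10.533,0.005
Croatia,MIGR->CO2,20.105,0.000
Bulgaria,MIGR->CO2,2.730,0.255
Netherlands,MIGR->CO2,0.577,0.749
Cyprus,MIGR->CO2,5.054,0.080
Poland,MIGR->CO2,4.831,0.185
Romania,MIGR->CO2,2.781,0.249
Austria,HEXP->MIGR,5.382,0.146
Belgium,HEXP->MIGR,5.358,0.069
France,HEXP->MIGR,13.041,0.005
Germany,HEXP->MIGR,4.914,0.178
Italy,HEXP->MIGR,2.318,0.509
Luxembourg,HEXP->MIGR,1.870,0.600
Czechia,HEXP->MIGR,4.178,0.124
Estonia,HEXP->MIGR,3.644,0.056
Finland,HEXP->MIGR,5.356,0.069
Hungary,HEXP->MIGR,9.284,0.026
Lithuania,HEXP->MIGR,0.521,0.914
Malta,HEXP->MIGR,7.295,0.063
Portugal,HEXP->MIGR,6.615,0.085
Slovak Republic,HEXP->MIGR,7.842,0.049
Sweden,HEXP->MIGR,4.147,0.246
Slovenia,HEXP->MIGR,7.578,0.056
Spain,HEXP->MIGR,0.201,0.654
Latvia,HEXP->MIGR,0.321,0.571
Ireland,HEXP->MIGR,0.126,0.939
Greece,HEXP->MIGR,0.314,0.855
Denmark,HEXP->MIGR,2.652,0.266
Croatia,HEXP->MIGR,5.733,0.125
Bulgaria,HEXP->MIGR,0.490,0.783
Netherlands,HEXP->MIGR,2.105,0.349
Cyprus,HEXP->MIGR,0.054,0.817
Poland,HEXP->MIGR,2.353,0.125
Romania,HEXP->MIGR,0.089,0.766
Austria,MIGR->HEXP,8.184,0.042
Belgium,MIGR->HEXP,0.175,0.916
France,MIGR->HEXP,0.589,0.899
Germany,MIGR->HEXP,3.356,0.340
Italy,MIGR->HEXP,6.618,0.085
Luxembourg,MIGR->HEXP,3.721,0.293
Czechia,MIGR->HEXP,0.529,0.768
Estonia,MIGR->HEXP,0.017,0.896
Finland,MIGR->HEXP,0.089,0.956
Hungary,MIGR->HEXP,5.698,0.127
Lithuania,MIGR->HEXP,0.054,0.997
Malta,MIGR->HEXP,3.175,0.365
Portugal,MIGR->HEXP,7.824,0.050
Slovak Republic,MIGR->HEXP,0.958,0.811
Sweden,MIGR->HEXP,20.038,0.000
Slovenia,MIGR->HEXP,12.951,0.005
Spain,MIGR->HEXP,4.872,0.027
Latvia,MIGR->HEXP,0.694,0.405
Ireland,MIGR->HEXP,3.727,0.155
Greece,MIGR->HEXP,1.999,0.368
Denmark,MIGR->HEXP,1.658,0.437
Croatia,MIGR->HEXP,0.627,0.890
Bulgaria,MIGR->HEXP,12.458,0.002
Netherlands,MIGR->HEXP,1.154,0.562
Cyprus,MIGR->HEXP,2.768,0.096
Poland,MIGR->HEXP,0.000,0.990
Romania,MIGR->HEXP,0.022,0.882
Austria,HEXP->CO2,4.330,0.228
Belgium,HEXP->CO2,2.393,0.495
France,HEXP->CO2,1.906,0.386
Germany,HEXP->CO2,5.996,0.050
Italy,HEXP->CO2,1.547,0.214
Luxembourg,HEXP->CO2,0.056,0.813
Czechia,HEXP->CO2,3.517,0.061
Estonia,HEXP->CO2,16.396,0.000
Finland,HEXP->CO2,4.909,0.027
Hungary,HEXP->CO2,3.804,0.283
Lithuania,HEXP->CO2,0.375,0.541
Malta,HEXP->CO2,24.973,0.000
Portugal,HEXP->CO2,0.003,0.958
Slovak Republic,HEXP->CO2,0.448,0.503
Sweden,HEXP->CO2,5.311,0.070
Slovenia,HEXP->CO2,2.808,0.094
Spain,HEXP->CO2,0.250,0.617
Latvia,HEXP->CO2,0.495,0.482
Ireland,HEXP->CO2,1.443,0.230
Greece,HEXP->CO2,1.775,0.183
Denmark,HEXP->CO2,3.754,0.289
Croatia,HEXP->CO2,8.376,0.039
Bulgaria,HEXP->CO2,0.025,0.874
Netherlands,HEXP->CO2,2.406,0.121
Cyprus,HEXP->CO2,0.106,0.745
Poland,HEXP->CO2,5.730,0.057
Romania,HEXP->CO2,6.063,0.109
Austria,CO2->HEXP,7.179,0.066
Belgium,CO2->HEXP,3.064,0.382
France,CO2->HEXP,7.057,0.029
Germany,CO2->HEXP,9.144,0.010
Italy,CO2->HEXP,1.878,0.171
Luxembourg,CO2->HEXP,0.296,0.587
Czechia,CO2->HEXP,1.664,0.197
Estonia,CO2->HEXP,4.346,0.114
Finland,CO2->HEXP,2.106,0.147
Hungary,CO2->HEXP,12.356,0.006
Lithuania,CO2->HEXP,9.666,0.002
Malta,CO2->HEXP,3.257,0.354
Portugal,CO2->HEXP,0.015,0.903
Slovak Republic,CO2->HEXP,1.570,0.210
Sweden,CO2->HEXP,8.060,0.018
Slovenia,CO2->HEXP,1.075,0.300
Spain,CO2->HEXP,0.449,0.503
Latvia,CO2->HEXP,2.017,0.156
Ireland,CO2->HEXP,0.163,0.686
Greece,CO2->HEXP,0.494,0.482
Denmark,CO2->HEXP,0.776,0.855
Croatia,CO2->HEXP,19.483,0.000
Bulgaria,CO2->HEXP,0.015,0.901
Netherlands,CO2->HEXP,1.041,0.308
Cyprus,CO2->HEXP,0.231,0.631
Poland,CO2->HEXP,8.332,0.016
Romania,CO2->HEXP,4.632,0.201
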