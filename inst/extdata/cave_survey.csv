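cave,area,subarea,cluster,lat,lon,N,Na_mean,Na_sd,Ar,PAr,Ho,He,Fis
1,H,S,1,65°34′802″,17°03′032″,26,2.11,0.60,1.95,0,0.31,0.31,0.005
2,H,S,1,65°34′794″,17°03′035″,30,2.11,0.78,1.86,0.01,0.27,0.32,0.127
3,H,S,1,65°34′796″,17°03′087″,15,2.22,0.83,2.02,0.01,0.25,0.26,0.033
4,H,S,1,65°34′812″,17°03′012″,17,1.89,0.60,1.83,0,0.49,0.33,-0.515
5,H,N,5,65°35′278″,17°03′487″,56,3.33,2.06,2.78,0,0.49,0.51,0.038
6,H,N,5,65°35′289″,17°03′502″,15,2.56,1.24,2.38,0,0.42,0.43,0.027
7,H,C,2,65°35′048″,17°03′385″,78,4.11,2.80,2.87,0.07,0.46,0.44,-0.044
8,H,C,2,65°34′986″,17°03′462″,9,2.78,0.97,2.75,0,0.53,0.48,0.109
9,H,C,2,65°34′965″,17°03′427″,21,3.56,1.88,3.02,0,0.51,0.51,-0.010
10,H,N,5,65°35′244″,17°03′481″,30,3.11,1.76,2.70,0,0.53,0.51,-0.032
11,H,N,5,65°35′271″,17°03′528″,48,3.33,1.58,2.82,0.02,0.48,0.51,0.053
12,H,C,2,65°35′023″,17°03′337″,42,3.22,1.64,2.81,0.02,0.50,0.50,-0.011
13,H,C,2,65°35′021″,17°03′334″,14,3.33,1.50,2.96,0.06,0.55,0.55,-0.016
17,V,W,4,65°37′018″,17°04′262″,10,2.22,0.83,2.20,0,0.41,0.38,-0.076
17b,V,W,4,65°37′014″,17°04′243″,16,2.22,0.83,2.19,0,0.40,0.39,-0.039
18,V,W,4,65°37′030″,17°04′309″,60,2.56,0.88,2.27,0,0.40,0.38,-0.048
19,V,W,4,65°36′946″,17°04′240″,26,2.89,1.05,2.66,0.01,0.47,0.45,-0.049
20,V,W,4,65°36′908″,17°04′239″,43,3.00,1.12,2.64,0.01,0.42,0.45,0.066
21,V,E,3,65°37′001″,17°03′123″,35,3.11,1.54,2.58,0.07,0.50,0.47,-0.077
22,V,E,3,65°37′021″,17°03′166″,71,3.78,2.17,2.69,0.02,0.44,0.47,0.049
23,V,E,3,65°37′034″,17°03′246″,38,3.00,1.58,2.43,0.02,0.38,0.38,-0.001
24,V,E,3,65°37′034″,17°03′229″,22,3.11,1.54,2.72,0.06,0.48,0.50,0.030
25,H,C,2,65°35′055″,17°03′416″,182,4.33,3.16,2.87,0.05,0.44,0.46,0.040
26,H,CS,1,65°34′896″,17°03′134″,69,3.44,1.24,2.65,0.05,0.43,0.41,-0.047
Generalist,L,Lake,,,,50,6.56,4.50,3.84,0.44,0.55,0.59,0.082
Krús,L,Lake,,65°33′052″,16°56′038″,49,5.33,3.20,3.78,0.23,0.56,0.61,0.083
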