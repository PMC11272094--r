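energy_keV,weight
2,2.51072231177458e-27
2.8135593220339,2.6021286764478e-10
3.6271186440678,2.69091789071281e-05
4.4406779661017,0.00238807948058216
5.25423728813559,0.0181731705047349
6.06779661016949,0.0479495467324581
6.88135593220339,0.0745054900972333
7.69491525423729,0.0918520580903621
8.50847457627119,0.35132745069798
9.32203389830508,0.174219347944954
10.135593220339,0.110014078602258
10.9491525423729,0.0849233049227031
11.7627118644068,0.0573509383516319
12.5762711864407,0.0379294349939518
13.3898305084746,0.0308491500755345
14.2033898305085,0.025094542773669
15.0169491525424,0.0204555581946454
15.8305084745763,0.0167275620384521
16.6440677966102,0.0137316247317929
17.4576271186441,0.0113192859329589
18.271186440678,0.00937073373640391
19.0847457627119,0.00779070230398905
19.8983050847458,0.00650400869231568
20.7118644067797,0.00545149864171706
21.5254237288136,0.00458663959059795
22.3389830508475,0.00387276967517265
23.1525423728814,0.00328092453212891
23.9661016949153,0.00278814113133853
24.7796610169492,0.00237614214822682
25.5932203389831,0.00203031812793352
26.406779661017,0.00173894020271068
27.2203389830508,0.00149255031309225
28.0338983050847,0.00128348777511426
28.8474576271186,0.00110552056306335
29.6610169491525,0.000953557119225604
30.4745762711864,0.000823420230659557
31.2881355932203,0.000711668885945175
32.1016949152542,0.000615457348391694
32.9152542372881,0.000532423203709635
33.728813559322,0.000460598053224366
34.5423728813559,0.00039833597694439
35.3559322033898,0.000344255997034652
36.1694915254237,0.000297195616604577
36.9830508474576,0.000256173155199902
37.7966101694915,0.000220357099042533
38.6101694915254,0.000189041066985005
39.4237288135593,0.000161623289475964
40.2372881355932,0.000137589728018282
41.0508474576271,0.000116500142087378
41.864406779661,9.79765509634283e-05
42.6779661016949,8.16936483078548e-05
43.4915254237288,6.73708143593342e-05
44.3050847457627,5.47654395233907e-05
45.1186440677966,4.36673278629756e-05
45.9322033898305,3.38939926328833e-05
46.7457627118644,2.52866909099324e-05
47.5593220338983,1.77070723941436e-05
48.3728813559322,1.10343400269486e-05
49.1864406779661,5.16283831091097e-06
50,0
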