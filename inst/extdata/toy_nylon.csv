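energy_keV,delta,beta
2,6.100175e-05,6.89585e-08
2.17738868717336,5.14671785934242e-05,5.81802888447404e-08
2.37051074751527,4.34228603665865e-05,4.908671171875e-08
2.58076164223132,3.66358687992464e-05,4.14144603817568e-08
2.80966060204271,3.09096837781879e-05,3.49413816622993e-08
3.05886160484225,2.6078501277066e-05,2.94800449219007e-08
3.33016532700624,2.20024324330957e-05,2.48723149243691e-08
3.62553215472018,1.85634530078872e-05,2.09847729654377e-08
3.9470963493355,1.56619859474125e-05,1.77048536796837e-08
4.2971814691132,1.32140180877299e-05,1.49375856643903e-08
4.67831715878905,1.11486675195045e-05,1.26028415437877e-08
5.09325742827816,9.40613117336871e-06,1.06330178481559e-08
5.54500055259728,7.93595319762042e-06,8.97107752774483e-09
6.03681073679769,6.69556398842633e-06,7.56889842169933e-09
6.57224170245499,5.64904756955395e-06,6.3858798612349e-09
7.15516236614726,4.76610163060866e-06,5.38776706068805e-09
7.78978479546882,4.02116011125822e-06,4.54565925620494e-09
8.48069464458444,3.39265292551246e-06,3.83517287231844e-09
9.23288428924495,2.86238139107244e-06,3.23573548556015e-09
10.0517889006913,2.4149912790505e-06,2.72999014153535e-09
10.94332571911,2.03752822600096e-06,2.30329277721848e-09
11.9139368104217,1.7190626350348e-06,1.9432881961263e-09
12.9706356153553,1.45037320487721e-06,1.63955231855685e-09
14.1210576271613,1.22367992332241e-06,1.38329034810359e-09
15.3735155641521,1.03241879380218e-06,1.16708211473289e-09
16.7370594357342,8.7105177218398e-07,9.84667220729717e-10
18.2215419359579,7.34906410440873e-07,8.30763768324465e-10
19.8376896371049,6.20040564010257e-07,7.00915420185508e-10
21.5971804977442,5.23128245387769e-07,5.91362364351391e-10
23.5127282453148,4.41363318800476e-07,4.98932447339668e-10
25.598174242965,3.72378247399304e-07,4.2094932314704e-10
27.8685875044623,3.14175540262472e-07,3.55154958557578e-10
30.3403735798586,2.65069914229906e-07,2.9964425086859e-10
33.0313930986989,2.23639495840926e-07,2.52809864863656e-10
35.9610908273416,1.88684650407378e-07,2.13295691764862e-10
39.1506361729337,1.59193246101208e-07,1.79957582549191e-10
42.6230761492931,1.34311347263936e-07,1.51830218646188e-10
46.4035019099998,1.13318488350849e-07,1.28099160744438e-10
50.5192300520306,9.56068125568527e-08,1.08077266368616e-10
55,8.06634710743801e-08,9.11847933884297e-11
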