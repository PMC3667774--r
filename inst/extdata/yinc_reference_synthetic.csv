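p_tm_kpa,yinc_kpa
0.25,18.796559
0.3,29.409389
0.35,42.953357
0.4,59.372222
0.45,78.561154
0.5,100.39656
0.55,124.751213
0.6,151.501533
0.65,180.530824
0.7,211.730451
0.75,245
0.8,280.246943
0.85,317.386086
0.9,356.338952
0.95,397.033155
1,439.401808
1.05,483.382986
1.1,528.919232
1.15,575.957124
1.2,624.446879
1.25,674.342013
1.3,725.599028
1.35,778.177144
1.4,832.038055
1.45,887.145713
1.5,943.466136
1.55,1000.967235
1.6,1059.618665
1.65,1119.391684
1.7,1180.259027
1.75,1242.194799
1.8,1305.174371
1.85,1369.174288
1.9,1434.172189
1.95,1500.146731
2,1567.077519
2.05,1634.945044
2.1,1703.730627
2.15,1773.416364
2.2,1843.985081
2.25,1915.420289
2.3,1987.706141
2.35,2060.827397
2.4,2134.769389
2.45,2209.517988
2.5,2285.059575
2.55,2361.381013
2.6,2438.469621
2.65,2516.313153
2.7,2594.899771
2.75,2674.218029
2.8,2754.256848
2.85,2835.005508
2.9,2916.453619
2.95,2998.591115
3,3081.408231
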