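# 63|pentagonal orthocupolarotunda (J32)|Johnson
1.61803399144 -1.07905062722e-08 0.340260310568
1.30901700557 0.95105650827 0.340260302702
0.500000016455 1.5388417678 0.340260302719
-0.499999983545 1.53884177675 0.340260310613
-1.30901698318 0.951056531695 0.340260323368
-1.61803398606 1.81647643613e-08 0.340260336113
-1.3090170002 -0.951056500895 0.34026034398
-0.500000011083 -1.53884176043 0.340260343963
0.499999988917 -1.53884176937 0.340260336069
1.30901698855 -0.951056524321 0.340260323313
0.809017003563 0.262865558205 0.865991426225
1.44474153866e-08 0.850650817736 0.865991426242
-0.809016985187 0.262865572682 0.865991438998
-0.499999999322 -0.688190946378 0.865991446864
0.500000000678 -0.688190955325 0.86599143897
8.28642746599e-09 1.37638191494 -0.510390499926
-0.500000002021 0.688190953482 -1.03612160064
-1.3090169946 0.425325410358 -0.510390479287
1.30901699415 0.425325386933 -0.510390499953
0.809016983844 -0.262865574526 -1.03612160067
0.809016980383 -1.11351637718 -0.510390479331
0.499999997979 0.688190944534 -1.03612160853
-0.809017004906 -0.262865560048 -1.0361215879
-1.57904103026e-08 -0.85065081958 -1.03612158791
-0.809017008367 -1.1135163627 -0.510390466559
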