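# 106|trigyrate rhombicosidodecahedron (J75)|Johnson
-1.894427193 -0.861803397031 -0.809016991663
-2.20344418573 -0.361803396708 3.1391094979e-09
-2.11803398897 0.500000002071 -0.499999997002
-2.11803398755 0.500000002095 0.500000002998
-1.80901699623 1.7484015652e-09 -1.3090169918
-1.80901699252 1.80987253901e-09 1.30901699695
-1.39442719335 -1.67082039189 -0.49999999798
-1.8944271907 -0.861803396993 0.809016997087
-1.61803398861 1.30901699595 -0.809016992107
-1.61803398631 1.30901699599 0.809016996643
-1.39442719193 -1.67082039187 0.50000000202
-1.30901699747 -0.809016993126 -1.61803398687
-1.30901699287 -0.80901699305 1.61803399063
-1.30901699588 0.809016995624 -1.61803398691
-1.30901699128 0.8090169957 1.61803399059
-1.3090169926 1.80901699566 1.81735280788e-09
-0.809016997826 -1.61803398798 -1.30901699319
-0.809016994106 -1.61803398792 1.30901699556
-0.809016994643 1.61803398951 -1.30901699326
-0.499999996255 1.39442719153 1.67082039393
-0.500000002793 -2.11803398827 -0.49999999924
-0.500000001373 -2.11803398825 0.50000000076
-0.500000003501 -0.499999999558 -2.11803398803
-0.499999997482 -0.499999999459 2.11803398947
-0.500000002518 0.500000000442 -2.11803398805
-0.499999996499 0.500000000541 2.11803398945
-0.499999998627 2.11803398923 -0.499999999339
-0.809016991287 1.89442719182 0.86180339998
-3.85761468784e-09 -1.30901699442 -1.80901699434
1.28282375739e-09 -1.30901699433 1.80901699441
-1.2828233225e-09 1.30901699433 -1.80901699441
0.500000003745 1.39442719055 1.67082039251
0.499999997207 -2.11803398925 -0.500000000661
0.499999998627 -2.11803398923 0.499999999339
0.361803395744 -4.07563891283e-10 -2.20344418589
0.500000002518 -0.500000000442 2.11803398805
0.861803396979 0.809016993483 -1.89442719224
0.500000003501 0.499999999558 2.11803398803
0.500000001373 2.11803398825 -0.50000000076
2.6810936456e-09 2.20344418538 0.361803398823
0.809016990924 -1.61803398958 -1.30901699549
0.809016994643 -1.61803398951 1.30901699326
0.809016994106 1.61803398792 -1.30901699556
0.809016997463 1.89442719022 0.861803397681
1.3090169926 -1.80901699566 -1.81735274331e-09
0.861803395388 -0.809016995267 -1.89442719221
1.30901699588 -0.809016995624 1.61803398691
1.67082039176 0.499999998324 -1.39442719339
1.30901699747 0.809016993126 1.61803398687
1.30901699615 1.80901699309 -1.90230343676e-09
1.61803398631 -1.30901699599 -0.809016996643
1.61803398861 -1.30901699595 0.809016992107
1.61803398889 1.30901699276 -0.809016996705
1.61803399119 1.3090169928 0.809016992045
1.67082039078 -0.500000001676 -1.39442719336
1.80901699623 -1.74840165321e-09 1.3090169918
2.11803398755 -0.500000002095 -0.500000002998
2.11803398897 -0.500000002071 0.499999997002
2.11803398853 0.499999997905 -0.500000003021
2.11803398995 0.499999997929 0.499999996979
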