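# 111|parabidiminished rhombicosidodecahedron (J80)|Johnson
-2.11803399014 -0.499999999998 -0.499999994109
-2.11803398737 -0.499999999972 0.500000005891
-2.11803399013 0.500000000002 -0.499999994135
-2.11803398736 0.500000000028 0.500000005865
-1.80901699801 -2.14052087134e-11 -1.30901698935
-1.618033991 -1.30901699438 -0.809016989851
-1.61803398651 -1.30901699434 0.809016998899
-1.61803399099 1.30901699437 -0.809016989919
-1.6180339865 1.30901699441 0.809016998831
-1.30901699439 -1.80901699437 3.67975492923e-09
-1.30901699887 -0.809016994408 -1.6180339851
-1.30901699886 0.809016994342 -1.61803398514
-1.30901699436 1.80901699438 3.585456628e-09
-0.809016998019 -1.61803398878 -1.30901699209
-0.809016990754 -1.61803398871 1.30901699666
-0.809016997996 1.61803398872 -1.30901699217
-0.809016990731 1.61803398879 1.30901699658
-0.500000001402 -2.11803398876 -0.499999998557
-0.499999998627 -2.11803398873 0.500000001443
-0.500000005881 -0.500000000052 -2.11803398735
-0.500000005874 0.499999999948 -2.11803398738
-0.500000001373 2.11803398874 -0.499999998668
-0.499999998598 2.11803398877 0.500000001332
-5.02933624011e-09 -1.30901699442 -1.80901699434
5.01093920064e-09 -1.30901699433 1.80901699441
-5.01093912042e-09 1.30901699433 -1.80901699441
5.02933621543e-09 1.30901699442 1.80901699434
0.499999998598 -2.11803398877 -0.500000001332
0.500000001373 -2.11803398874 0.499999998668
0.500000005874 -0.499999999948 2.11803398738
0.500000005881 0.500000000052 2.11803398735
0.499999998627 2.11803398873 -0.500000001443
0.500000001402 2.11803398876 0.499999998557
0.809016990731 -1.61803398879 -1.30901699658
0.809016997996 -1.61803398872 1.30901699217
0.809016990754 1.61803398871 -1.30901699666
0.809016998019 1.61803398878 1.30901699209
1.30901699436 -1.80901699438 -3.58545655219e-09
1.30901699886 -0.809016994342 1.61803398514
1.30901699887 0.809016994408 1.6180339851
1.30901699439 1.80901699437 -3.6797549654e-09
1.6180339865 -1.30901699441 -0.809016998831
1.61803399099 -1.30901699437 0.809016989919
1.61803398651 1.30901699434 -0.809016998899
1.618033991 1.30901699438 0.809016989851
1.80901699801 2.14052601307e-11 1.30901698935
2.11803398736 -0.500000000028 -0.500000005865
2.11803399013 -0.500000000002 0.499999994135
2.11803398737 0.499999999972 -0.500000005891
2.11803399014 0.499999999998 0.499999994109
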