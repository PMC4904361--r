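# 104|parabigyrate rhombicosidodecahedron (J73)|Johnson
-2.11803398832 -0.499999998651 -0.50000000315
-2.11803398926 -0.500000000972 0.49999999685
-2.11803398824 0.500000001349 -0.500000000829
-2.11803398918 0.499999999028 0.499999999171
-1.80901699315 3.19986635237e-09 -1.30901699607
-1.6708203946 -0.500000003089 1.39442718827
-1.61803398811 -1.30901699235 -0.809016998934
-1.61803398963 -1.30901699611 0.809016989816
-1.61803398787 1.3090169964 -0.809016992856
-1.61803398939 1.30901699264 0.809016995894
-1.30901699454 -1.80901699426 -5.42918016742e-09
-1.30901699293 -0.809016990502 -1.61803399186
-0.861803400726 -0.809016998696 1.89442718831
-1.30901699278 0.809016998248 -1.6180339881
-1.67082039452 0.499999996911 1.39442719059
-1.30901699421 1.80901699449 2.97020195536e-09
-0.809016993289 -1.61803398564 -1.30901699889
-0.809016995748 -1.61803399172 1.30901698986
-0.809016993002 1.61803399186 -1.30901699138
-0.80901699546 1.61803398578 1.30901699737
-0.499999999719 -2.11803398754 -0.500000005387
-0.500000000658 -2.11803398987 0.499999994613
-0.499999998055 -0.499999995038 -2.11803399038
-0.361803400945 -5.08317812421e-09 2.20344418504
-0.499999997966 0.500000004962 -2.11803398806
-0.861803400582 0.809016990054 1.89442719207
-0.499999999342 2.11803398996 -0.499999995553
-0.500000000281 2.11803398763 0.500000004447
1.58265391192e-09 -1.30901699018 -1.80901699741
-1.81557057439e-09 -1.30901699857 1.80901699134
1.81557052405e-09 1.30901699857 -1.80901699134
-1.58265378709e-09 1.30901699018 1.80901699741
0.500000000281 -2.11803398763 -0.500000004447
0.499999999342 -2.11803398996 0.499999995553
0.361803400945 5.08317809627e-09 -2.20344418504
0.499999997966 -0.500000004962 2.11803398806
0.861803400726 0.809016998696 -1.89442718831
0.499999998055 0.499999995038 2.11803399038
0.500000000658 2.11803398987 -0.499999994613
0.499999999719 2.11803398754 0.500000005387
0.80901699546 -1.61803398578 -1.30901699737
0.809016993002 -1.61803399186 1.30901699138
0.809016995748 1.61803399172 -1.30901698986
0.809016993289 1.61803398564 1.30901699889
1.30901699421 -1.80901699449 -2.97020187355e-09
0.861803400582 -0.809016990054 -1.89442719207
1.30901699278 -0.809016998248 1.6180339881
1.6708203946 0.500000003089 -1.39442718827
1.30901699293 0.809016990502 1.61803399186
1.30901699454 1.80901699426 5.42918010873e-09
1.61803398939 -1.30901699264 -0.809016995894
1.61803398787 -1.3090169964 0.809016992856
1.61803398963 1.30901699611 -0.809016989816
1.61803398811 1.30901699235 0.809016998934
1.67082039452 -0.499999996911 -1.39442719059
1.80901699315 -3.19986641169e-09 1.30901699607
2.11803398918 -0.499999999028 -0.499999999171
2.11803398824 -0.500000001349 0.500000000829
2.11803398926 0.500000000972 -0.49999999685
2.11803398832 0.499999998651 0.50000000315
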