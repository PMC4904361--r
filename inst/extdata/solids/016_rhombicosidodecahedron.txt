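# 16|rhombicosidodecahedron|Archimedean
-2.11803398876 -0.499999999935 -0.500000000037
-2.11803398877 -0.499999999937 0.499999999963
-2.11803398873 0.500000000065 -0.500000000035
-2.11803398874 0.500000000063 0.499999999965
-1.80901699435 5.71627763894e-11 -1.30901699441
-1.8090169944 5.19927624695e-11 1.30901699434
-1.61803398878 -1.30901699432 -0.809016994405
-1.6180339888 -1.30901699433 0.809016994345
-1.6180339887 1.30901699443 -0.8090169944
-1.61803398872 1.30901699442 0.80901699435
-1.30901699443 -1.80901699434 -2.60178531858e-11
-1.30901699437 -0.809016994332 -1.61803398877
-1.30901699443 -0.809016994339 1.61803398873
-1.30901699432 0.809016994418 -1.61803398877
-1.30901699438 0.809016994411 1.61803398873
-1.30901699432 1.80901699441 -1.88730696368e-11
-0.809016994401 -1.61803398872 -1.30901699439
-0.809016994446 -1.61803398873 1.30901699436
-0.809016994304 1.61803398878 -1.30901699439
-0.809016994349 1.61803398877 1.30901699436
-0.500000000055 -2.11803398873 -0.500000000013
-0.500000000072 -2.11803398874 0.499999999987
-0.499999999979 -0.499999999981 -2.11803398876
-0.500000000051 -0.499999999989 2.11803398874
-0.499999999949 0.500000000019 -2.11803398876
-0.500000000021 0.500000000011 2.11803398874
-0.499999999928 2.11803398877 -0.500000000004
-0.499999999945 2.11803398876 0.499999999996
-8.47387133091e-12 -1.30901699437 -1.80901699438
-7.05115873648e-11 -1.30901699438 1.80901699437
7.05117989332e-11 1.30901699438 -1.80901699437
8.47408289931e-12 1.30901699437 1.80901699438
0.499999999945 -2.11803398876 -0.499999999996
0.499999999928 -2.11803398877 0.500000000004
0.500000000021 -0.500000000011 -2.11803398874
0.499999999949 -0.500000000019 2.11803398876
0.500000000051 0.499999999989 -2.11803398874
0.499999999979 0.499999999981 2.11803398876
0.500000000072 2.11803398874 -0.499999999987
0.500000000055 2.11803398873 0.500000000013
0.809016994349 -1.61803398877 -1.30901699436
0.809016994304 -1.61803398878 1.30901699439
0.809016994446 1.61803398873 -1.30901699436
0.809016994401 1.61803398872 1.30901699439
1.30901699432 -1.80901699441 1.88730595208e-11
1.30901699438 -0.809016994411 -1.61803398873
1.30901699432 -0.809016994418 1.61803398877
1.30901699443 0.809016994339 -1.61803398873
1.30901699437 0.809016994332 1.61803398877
1.30901699443 1.80901699434 2.60178430698e-11
1.61803398872 -1.30901699442 -0.80901699435
1.6180339887 -1.30901699443 0.8090169944
1.6180339888 1.30901699433 -0.809016994345
1.61803398878 1.30901699432 0.809016994405
1.8090169944 -5.19927356229e-11 -1.30901699434
1.80901699435 -5.71627495428e-11 1.30901699441
2.11803398874 -0.500000000063 -0.499999999965
2.11803398873 -0.500000000065 0.500000000035
2.11803398877 0.499999999937 -0.499999999963
2.11803398876 0.499999999935 0.500000000037
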