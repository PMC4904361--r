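# 105|metabigyrate rhombicosidodecahedron (J74)|Johnson
-1.89442718956 -0.861803398799 -0.80901699782
-2.20344418534 -0.361803399094 -3.7973266252e-09
-2.11803398796 0.499999999953 -0.500000003373
-2.11803398963 0.499999999626 0.499999996627
-1.80901699219 2.47589132952e-10 -1.3090169974
-1.80901699656 -6.07084890672e-10 1.30901699135
-1.39442719 -1.67082039323 -0.500000002874
-1.89442719227 -0.861803399327 0.80901699093
-1.61803398753 1.30901699448 -0.809016996649
-1.61803399023 1.30901699395 0.809016992101
-1.39442719167 -1.67082039355 0.499999997126
-1.30901699159 -0.809016993977 -1.6180339912
-1.309016997 -0.809016995033 1.6180339863
-1.30901699175 0.809016994773 -1.61803399067
-1.30901699716 0.809016993717 1.61803398683
-1.30901699455 1.80901699424 -1.59517338067e-09
-0.809016992028 -1.6180339884 -1.30901699625
-0.8090169964 -1.61803398926 1.3090169925
-0.80901699235 1.6180339891 -1.3090169952
-0.809016996721 1.61803398824 1.30901699355
-0.499999998955 -2.11803398864 -0.500000001526
-0.500000000624 -2.11803398896 0.499999998474
-0.499999996414 -0.499999999358 -2.11803398975
-0.500000003487 -0.500000000741 2.11803398775
-0.499999996513 0.500000000642 -2.11803398942
-0.500000003586 0.499999999259 2.11803398808
-0.499999999376 2.11803398886 -0.500000000143
-0.500000001045 2.11803398854 0.499999999857
3.15068326238e-09 -1.30901699378 -1.8090169948
-2.89054984445e-09 -1.30901699497 1.80901699395
2.89054978503e-09 1.30901699497 -1.80901699395
-3.15068320621e-09 1.30901699378 1.8090169948
0.500000001045 -2.11803398854 -0.499999999857
0.499999999376 -2.11803398886 0.500000000143
0.361803402554 7.55278087177e-10 -2.20344418477
0.499999996513 -0.500000000642 2.11803398942
0.861803401958 0.809016995079 -1.8944271893
0.499999996414 0.499999999358 2.11803398975
0.500000000624 2.11803398896 -0.499999998474
0.499999998955 2.11803398864 0.500000001526
0.809016996721 -1.61803398824 -1.30901699355
0.80901699235 -1.6180339891 1.3090169952
0.8090169964 1.61803398926 -1.3090169925
0.809016992028 1.6180339884 1.30901699625
1.30901699455 -1.80901699424 1.59517338704e-09
0.861803402119 -0.809016993671 -1.89442718983
1.30901699175 -0.809016994773 1.61803399067
1.67082039553 0.500000000621 -1.39442718805
1.30901699159 0.809016993977 1.6180339912
1.3090169942 1.80901699451 2.77630386925e-09
1.61803399023 -1.30901699395 -0.809016992101
1.61803398753 -1.30901699448 0.809016996649
1.61803398997 1.3090169948 -0.809016991246
1.61803398727 1.30901699427 0.809016997504
1.67082039563 -0.499999999379 -1.39442718837
1.80901699219 -2.47589407099e-10 1.3090169974
2.11803398963 -0.499999999626 -0.499999996627
2.11803398796 -0.499999999953 0.500000003373
2.11803398954 0.500000000374 -0.4999999963
2.11803398787 0.500000000047 0.5000000037
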