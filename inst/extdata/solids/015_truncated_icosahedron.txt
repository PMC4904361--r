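# 15|truncated icosahedron|Archimedean
-0.80901699277 -1.00000000117 -2.11803398881
-0.499999996996 -1.80901699507 -1.6180339889
0.80901699598 -0.999999998422 -2.11803398888
7.41299806097e-10 -0.499999999768 -2.42705098317
0.500000003004 -1.80901699337 -1.61803398895
-1.61803398798 -0.500000002579 -1.80901699435
-2.11803398742 -0.809016997881 -0.999999999982
-2.11803399017 0.809016990869 -0.999999999828
-1.61803398968 0.499999997421 -1.80901699425
-2.42705098315 -4.07949269166e-09 -0.499999999891
-0.999999996435 -2.11803399037 -0.809016994533
-1.80901699165 -1.61803399178 -0.500000000073
-0.999999996362 -2.11803399053 0.809016994217
-1.8090169916 -1.61803399187 0.499999999927
-0.499999995873 -2.42705098398 -2.0963254892e-10
-0.499999996851 -1.80901699538 1.6180339886
-0.809016992579 -1.00000000158 2.11803398869
0.500000003149 -1.80901699368 1.61803398855
9.59243256558e-10 -0.500000000232 2.42705098308
0.809016996171 -0.999999998827 2.11803398862
1.61803398952 -0.499999997075 -1.8090169945
1.61803398782 0.500000002925 -1.8090169944
2.11803399008 -0.809016990678 -1.00000000017
2.4270509831 4.17511578173e-09 -0.500000000109
2.11803398733 0.809016998072 -1.00000000002
-1.80901699715 1.61803398572 -0.499999999764
-1.00000000364 2.11803398713 -0.809016994128
-1.8090169971 1.61803398563 0.500000000236
-1.00000000357 2.11803398697 0.809016994622
-0.500000004127 2.42705098227 2.54531291412e-10
-9.59243044076e-10 0.500000000232 -2.42705098308
-0.809016996171 0.999999998827 -2.11803398862
0.809016992579 1.00000000158 -2.11803398869
-0.500000003149 1.80901699368 -1.61803398855
0.499999996851 1.80901699538 -1.6180339886
-2.4270509831 -4.17511568775e-09 0.500000000109
-2.11803398733 -0.809016998072 1.00000000002
-1.61803398782 -0.500000002925 1.8090169944
-2.11803399008 0.809016990678 1.00000000017
-1.61803398952 0.499999997075 1.8090169945
1.00000000357 -2.11803398697 -0.809016994622
0.500000004127 -2.42705098227 -2.54531460945e-10
1.00000000364 -2.11803398713 0.809016994128
1.8090169971 -1.61803398563 -0.500000000236
1.80901699715 -1.61803398572 0.499999999764
-7.41299632002e-10 0.499999999768 2.42705098317
-0.500000003004 1.80901699337 1.61803398895
-0.80901699598 0.999999998422 2.11803398888
0.80901699277 1.00000000117 2.11803398881
0.499999996996 1.80901699507 1.6180339889
1.61803398968 -0.499999997421 1.80901699425
2.42705098315 4.07949265593e-09 0.499999999891
2.11803399017 -0.809016990869 0.999999999828
1.61803398798 0.500000002579 1.80901699435
2.11803398742 0.809016997881 0.999999999982
1.8090169916 1.61803399187 -0.499999999927
0.499999995873 2.42705098398 2.09632505364e-10
0.999999996362 2.11803399053 -0.809016994217
0.999999996435 2.11803399037 0.809016994533
1.80901699165 1.61803399178 0.500000000073
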