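# 14|truncated dodecahedron|Archimedean
-1.30901699436 -1.61803398887 -2.11803398867
-2.11803398874 -1.30901699443 -1.61803398872
-1.61803398878 -2.1180339888 -1.30901699426
-1.61803398887 -2.11803398859 1.30901699449
-1.3090169945 -1.61803398854 2.11803398883
-2.11803398885 -1.30901699417 1.61803398878
-2.11803398865 1.30901699432 -1.61803398892
-1.61803398863 2.1180339887 -1.3090169946
-1.30901699425 1.61803398863 -2.11803398892
-1.61803398872 2.11803398891 1.30901699415
-2.11803398876 1.30901699458 1.61803398858
-1.30901699439 1.61803398896 2.11803398858
1.30901699439 -1.61803398896 -2.11803398858
2.11803398876 -1.30901699458 -1.61803398858
1.61803398872 -2.11803398891 -1.30901699415
1.30901699425 -1.61803398863 2.11803398892
1.61803398863 -2.1180339887 1.3090169946
2.11803398865 -1.30901699432 1.61803398892
2.11803398885 1.30901699417 -1.61803398878
1.3090169945 1.61803398854 -2.11803398883
1.61803398887 2.11803398859 -1.30901699449
1.30901699436 1.61803398887 2.11803398867
2.11803398874 1.30901699443 1.61803398872
1.61803398878 2.1180339888 1.30901699426
-0.499999999959 -1.30901699456 -2.61803398866
0.500000000041 -1.3090169946 -2.61803398863
8.06458642692e-11 -0.500000000231 -2.92705098309
-2.61803398872 -0.50000000001 -1.30901699442
-2.61803398869 0.49999999999 -1.3090169945
-2.92705098311 6.55414990705e-11 -0.500000000099
-1.30901699445 -2.61803398874 -0.499999999837
-1.30901699449 -2.61803398866 0.500000000163
-0.500000000105 -2.92705098311 2.14622800613e-10
-0.500000000135 -1.30901699415 2.61803398884
0.499999999865 -1.30901699419 2.61803398887
-1.16545549637e-10 -0.499999999769 2.92705098316
2.61803398878 -0.500000000198 -1.30901699425
2.61803398881 0.499999999802 -1.30901699433
2.92705098314 -1.44619374706e-10 -0.499999999901
-1.30901699426 2.61803398876 -0.500000000251
-1.3090169943 2.61803398884 0.499999999749
-0.499999999895 2.92705098314 -2.48307201589e-10
-0.499999999865 1.30901699419 -2.61803398887
0.500000000135 1.30901699415 -2.61803398884
1.16545696852e-10 0.499999999769 -2.92705098316
-2.61803398881 -0.499999999802 1.30901699433
-2.61803398878 0.500000000198 1.30901699425
-2.92705098314 1.44619425393e-10 0.499999999901
1.3090169943 -2.61803398884 -0.499999999749
1.30901699426 -2.61803398876 0.500000000251
0.499999999895 -2.92705098314 2.48307263807e-10
-0.500000000041 1.3090169946 2.61803398863
0.499999999959 1.30901699456 2.61803398866
-8.06457085828e-11 0.500000000231 2.92705098309
2.61803398869 -0.49999999999 1.3090169945
2.61803398872 0.50000000001 1.30901699442
2.92705098311 -6.5541682378e-11 0.500000000099
1.30901699449 2.61803398866 -0.500000000163
1.30901699445 2.61803398874 0.499999999837
0.500000000105 2.92705098311 -2.146229523e-10
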