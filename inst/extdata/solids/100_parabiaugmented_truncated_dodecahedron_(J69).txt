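# 100|parabiaugmented truncated dodecahedron (J69)|Johnson
-1.30901699465 -1.61803398771 -2.11803398938
-2.11803398896 -1.30901699358 -1.61803398911
-1.61803398891 -2.11803398811 -1.30901699521
-1.61803398856 -2.11803398941 1.30901699354
-1.30901699408 -1.61803398981 2.11803398812
-2.11803398852 -1.30901699519 1.61803398839
-2.11803398898 1.30901699517 -1.61803398781
-1.61803398894 2.11803398939 -1.3090169931
-1.30901699467 1.61803398979 -2.11803398777
-1.61803398859 2.11803398809 1.30901699565
-2.11803398854 1.30901699356 1.61803398969
-1.3090169941 1.61803398769 2.11803398973
1.3090169941 -1.61803398769 -2.11803398973
2.11803398854 -1.30901699356 -1.61803398969
1.61803398859 -2.11803398809 -1.30901699565
1.30901699467 -1.61803398979 2.11803398777
1.61803398894 -2.11803398939 1.3090169931
2.11803398898 -1.30901699517 1.61803398781
2.11803398852 1.30901699519 -1.61803398839
1.30901699408 1.61803398981 -2.11803398812
1.61803398856 2.11803398941 -1.30901699354
1.30901699465 1.61803398771 2.11803398938
2.11803398896 1.30901699358 1.61803398911
1.61803398891 2.11803398811 1.30901699521
-0.500000000348 -1.30901699308 -2.61803398933
0.499999999652 -1.30901699307 -2.61803398947
-3.95432255946e-10 -0.499999998543 -2.92705098337
-2.61803398892 -0.499999999367 -1.30901699427
-2.61803398893 0.500000000633 -1.30901699377
-2.92705098319 2.28521957375e-10 -0.499999999601
-1.30901699442 -2.61803398851 -0.500000001124
-1.30901699429 -2.61803398901 0.499999998876
-0.49999999998 -2.92705098313 -1.38839120632e-09
-0.499999999634 -1.30901699568 2.61803398817
0.500000000366 -1.30901699567 2.61803398803
4.02361761482e-10 -0.500000001457 2.92705098288
2.61803398857 -0.49999999933 -1.30901699498
2.61803398857 0.50000000067 -1.30901699448
2.92705098306 2.69088066055e-10 -0.500000000399
-1.30901699446 2.61803398899 -0.499999998519
-1.30901699432 2.61803398849 0.500000001481
-0.50000000002 2.92705098312 1.52467059687e-09
-0.500000000366 1.30901699567 -2.61803398803
0.499999999634 1.30901699568 -2.61803398817
-4.02361739036e-10 0.500000001457 -2.92705098288
-2.61803398857 -0.50000000067 1.30901699448
-2.61803398857 0.49999999933 1.30901699498
-2.92705098306 -2.69088212077e-10 0.500000000399
1.30901699432 -2.61803398849 -0.500000001481
1.30901699446 -2.61803398899 0.499999998519
0.50000000002 -2.92705098312 -1.52467068946e-09
-0.499999999652 1.30901699307 2.61803398947
0.500000000348 1.30901699308 2.61803398933
3.95432272612e-10 0.499999998543 2.92705098337
2.61803398893 -0.500000000633 1.30901699377
2.61803398892 0.499999999367 1.30901699427
2.92705098319 -2.28522360019e-10 0.499999999601
1.30901699429 2.61803398901 -0.499999998876
1.30901699442 2.61803398851 0.500000001124
0.49999999998 2.92705098313 1.38839109002e-09
0.500000000311 -2.20344418645 2.17082039209
-0.499999999689 -2.20344418646 2.17082039222
-0.809016994171 -2.70344418606 1.36180339764
1.38321022022e-10 -3.01246118018 0.861803397376
0.809016994579 -2.70344418605 1.36180339742
0.499999999689 2.20344418646 -2.17082039222
-0.500000000311 2.20344418645 -2.17082039209
-0.809016994579 2.70344418605 -1.36180339742
-1.38321108073e-10 3.01246118018 -0.861803397376
0.809016994171 2.70344418606 -1.36180339764
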