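# 99|augmented truncated dodecahedron (J68)|Johnson
-1.30901699412 -1.42070725067 -2.23998861993
-2.11803398855 -1.11169025655 -1.73998861987
-1.61803398853 -1.92070725102 -1.43097162578
-1.61803398873 -1.92070725208 1.18706236297
-1.30901699444 -1.42070725238 1.99607935757
-2.1180339888 -1.11169025786 1.49607935763
-2.11803398871 1.5063437322 -1.73998861881
-1.61803398878 2.31536072648 -1.43097162407
-1.30901699431 1.81536072683 -2.23998861862
-1.61803398898 2.31536072542 1.18706236468
-2.11803398895 1.50634373089 1.49607935869
-1.30901699463 1.81536072512 1.99607935888
1.30901699463 -1.42070725052 -2.23998861974
2.11803398895 -1.1116902563 -1.73998861955
1.61803398897 -1.92070725083 -1.43097162554
1.30901699431 -1.42070725223 1.99607935776
1.61803398877 -1.92070725188 1.18706236321
2.1180339887 -1.1116902576 1.49607935795
2.11803398879 1.50634373245 -1.73998861849
1.30901699444 1.81536072698 -2.23998861843
1.61803398872 2.31536072667 -1.43097162383
1.30901699412 1.81536072527 1.99607935907
2.11803398855 1.50634373114 1.49607935901
1.61803398852 2.31536072562 1.18706236492
-0.499999999728 -1.11169025605 -2.73998861975
0.500000000272 -1.11169025599 -2.73998861967
2.46928445038e-10 -0.302673261517 -3.04900561376
-2.61803398862 -0.302673262326 -1.4309716252
-2.61803398868 0.697326737674 -1.4309716248
-2.92705098309 0.197326737329 -0.62195463065
-1.30901699419 -2.42070725133 -0.621954631587
-1.30901699426 -2.42070725173 0.378045368413
-0.499999999829 -2.72972424586 -0.121954631651
-0.500000000122 -1.11169025816 2.49607935775
0.499999999878 -1.11169025811 2.49607935783
-1.92818118512e-10 -0.302673263885 2.80509635249
2.61803398888 -0.302673262016 -1.43097162481
2.61803398882 0.697326737984 -1.43097162441
2.92705098316 0.197326737675 -0.62195463021
-1.30901699449 2.81536072617 -0.621954629469
-1.30901699457 2.81536072577 0.378045370531
-0.500000000176 3.12437772039 -0.121954629283
-0.499999999883 1.5063437327 -2.73998861869
0.500000000117 1.50634373276 -2.73998861861
1.87807771767e-10 0.697326738483 -3.04900561335
-2.61803398882 -0.302673263385 1.18706236355
-2.61803398888 0.697326736615 1.18706236395
-2.92705098316 0.197326736924 0.37804536935
1.30901699456 -2.42070725117 -0.621954631391
1.30901699449 -2.42070725158 0.378045368609
0.500000000171 -2.7297242458 -0.121954631576
-0.500000000277 1.50634373059 2.49607935881
0.499999999723 1.50634373064 2.49607935889
-2.51938955415e-10 0.697326736115 2.8050963529
2.61803398868 -0.302673263075 1.18706236394
2.61803398862 0.697326736925 1.18706236434
2.92705098308 0.19732673727 0.37804536979
1.30901699426 2.81536072633 -0.621954629272
1.30901699418 2.81536072592 0.378045370728
0.499999999824 3.12437772045 -0.121954629208
0.499999999965 -2.00611744892 2.04886576197
-0.500000000035 -2.00611744898 2.04886576189
-0.80901699432 -2.50611744867 1.23984876729
1.10857179136e-10 -2.8151344428 0.739848767227
0.80901699443 -2.50611744858 1.23984876741
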