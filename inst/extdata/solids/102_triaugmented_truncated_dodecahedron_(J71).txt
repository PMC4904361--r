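# 102|triaugmented truncated dodecahedron (J71)|Johnson
-1.41471100745 -1.61803398873 -2.15840550939
-2.22372800185 -1.30901699413 -1.65840550956
-1.72372800206 -2.11803398857 -1.349388515
-1.7237280025 -2.11803398824 1.26864547375
-1.41471100816 -1.61803398821 2.07766246811
-2.22372800239 -1.30901699373 1.57766246794
-2.22372800131 1.30901699462 -1.65840550988
-1.7237280012 2.11803398893 -1.34938851553
-1.41471100679 1.61803398877 -2.15840550979
-1.72372800164 2.11803398926 1.26864547322
-2.22372800186 1.30901699502 1.57766246762
-1.4147110075 1.61803398929 2.07766246771
1.2033229813 -1.61803398926 -2.15840550895
2.01233997565 -1.30901699499 -1.65840550885
1.51233997544 -2.11803398922 -1.34938851446
1.20332298059 -1.61803398874 2.07766246855
1.512339975 -2.1180339889 1.26864547429
2.01233997511 -1.30901699459 1.57766246865
2.01233997619 1.30901699376 -1.65840550917
1.20332298196 1.61803398824 -2.15840550935
1.5123399763 2.11803398828 -1.34938851498
1.20332298125 1.61803398876 2.07766246815
2.01233997564 1.30901699416 1.57766246833
1.51233997586 2.1180339886 1.26864547377
-0.605694012929 -1.30901699458 -2.65840550929
0.394305987071 -1.30901699478 -2.65840550912
-0.105694012712 -0.500000000344 -2.96742250368
-2.72372800173 -0.499999999612 -1.34938851537
-2.72372800153 0.500000000388 -1.34938851549
-3.03274499614 5.50890474395e-10 -0.540371521109
-1.41471100793 -2.61803398853 -0.540371520515
-1.41471100809 -2.61803398841 0.459628479485
-0.605694013698 -2.92705098301 -0.0403715203409
-0.605694013808 -1.30901699393 2.57766246821
0.394305986192 -1.30901699414 2.57766246838
-0.105694013695 -0.499999999623 2.88667946257
2.51233997577 -0.500000000678 -1.34938851449
2.51233997597 0.499999999322 -1.34938851461
2.82135697011 -6.41052436676e-10 -0.540371520126
-1.41471100686 2.61803398897 -0.54037152116
-1.41471100703 2.61803398909 0.45962847884
-0.605694012506 2.92705098324 -0.0403715210625
-0.605694012395 1.30901699417 -2.65840550961
0.394305987605 1.30901699397 -2.65840550945
-0.105694012508 0.499999999656 -2.9674225038
-2.72372800217 -0.499999999289 1.26864547338
-2.72372800197 0.500000000711 1.26864547326
-3.03274499631 6.74141116487e-10 0.459628478891
1.20332298082 -2.61803398906 -0.540371520075
1.20332298066 -2.61803398894 0.459628479925
0.394305986302 -2.92705098321 -0.040371520173
-0.605694013275 1.30901699482 2.57766246789
0.394305986725 1.30901699461 2.57766246805
-0.105694013491 0.500000000377 2.88667946245
2.51233997533 -0.500000000355 1.26864547426
2.51233997553 0.499999999645 1.26864547414
2.82135696994 -5.1780166424e-10 0.459628479874
1.20332298189 2.61803398844 -0.540371520721
1.20332298172 2.61803398856 0.459628479279
0.394305987494 2.92705098304 -0.0403715208946
0.394305986085 -2.20344418519 2.13044887299
-0.605694013915 -2.20344418499 2.13044887282
-0.914711008256 -2.70344418503 1.32143187845
-0.10569401386 -3.01246117963 0.821431878629
0.703322980494 -2.70344418536 1.32143187873
2.06512638062 0.499999999303 -2.24381570569
2.06512638042 -0.500000000697 -2.24381570557
1.25610938606 -0.809016994969 -2.74381570566
0.756109386279 -5.30213885443e-10 -3.05283270022
1.25610938639 0.809016993781 -2.74381570586
-0.105694012633 3.01246117987 0.821431877886
-0.914711007155 2.70344418572 1.32143187779
-0.605694013017 2.20344418576 2.13044887228
0.394305986983 2.20344418556 2.13044887244
0.703322981595 2.70344418539 1.32143187806
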