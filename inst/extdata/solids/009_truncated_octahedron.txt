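# 9|truncated octahedron|Archimedean
1.41421356225 0.707106781424 8.98385292035e-09
1.41421356249 -0.70710678095 1.86411166719e-09
1.41421355966 -3.32283048442e-09 0.707106786611
1.41421356509 3.79691081359e-09 -0.707106775763
-1.41421356249 0.70710678095 -1.8641115946e-09
-1.41421356225 -0.707106781424 -8.98385281525e-09
-1.41421356509 -3.7969109076e-09 0.707106775763
-1.41421355966 3.32283043568e-09 -0.707106786611
0.70710678095 1.41421356249 9.83173236336e-09
-0.707106781424 1.41421356225 4.40775025134e-09
-2.94903128839e-09 1.41421355881 0.707106788306
2.47495073752e-09 1.41421356593 -0.707106774067
0.707106781424 -1.41421356225 -4.40774998314e-09
-0.70710678095 -1.41421356249 -9.83173236196e-09
-2.47495091509e-09 -1.41421356593 0.707106774067
2.94903130539e-09 -1.41421355881 -0.707106788306
0.707106775763 -7.00122118166e-09 1.41421356509
-0.707106786611 -7.23826139485e-09 1.41421355966
-5.54250236029e-09 0.707106774067 1.41421356593
-5.30546228716e-09 -0.707106788306 1.41421355881
0.707106786611 7.23826134569e-09 -1.41421355966
-0.707106775763 7.00122113489e-09 -1.41421356509
5.30546215315e-09 0.707106788306 -1.41421355881
5.54250236102e-09 -0.707106774067 -1.41421356593
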