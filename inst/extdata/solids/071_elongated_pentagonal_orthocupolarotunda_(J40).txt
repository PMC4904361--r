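# 71|elongated pentagonal orthocupolarotunda (J40)|Johnson
1.61803398521 -1.36951934358e-09 0.814471666555
1.30901699202 0.951056515309 0.814471664466
0.499999998374 1.53884176861 0.814471660492
-0.500000001626 1.53884176985 0.81447165615
-1.30901699673 0.95105651856 0.814471653099
-1.61803399229 2.64850535673e-09 0.814471652504
-1.30901699909 -0.95105651403 0.814471654592
-0.500000005447 -1.53884176733 0.814471658566
0.499999994553 -1.53884176857 0.814471662908
1.30901698966 -0.951056517281 0.81447166596
0.809016988882 0.262865556107 1.34020277495
-4.76286439161e-09 0.850650809404 1.34020277098
-0.809016999868 0.262865558116 1.34020276793
-0.500000006674 -0.688190958562 1.34020277002
0.499999993326 -0.688190959804 1.34020277436
1.61803398956 -2.15468235679e-09 -0.185528333445
1.30901699636 0.951056514524 -0.185528335534
0.500000002716 1.53884176782 -0.185528339508
-0.499999997284 1.53884176906 -0.18552834385
-1.30901699239 0.951056517775 -0.185528346901
-1.61803398794 1.86334245056e-09 -0.185528347496
-1.30901699475 -0.951056514815 -0.185528345408
-0.500000001105 -1.53884176811 -0.185528341434
0.499999998895 -1.53884176935 -0.185528337092
1.309016994 -0.951056518066 -0.18552833404
6.20798370051e-09 1.37638191966 -1.0361791499
-0.499999992364 0.68819095963 -1.56191026365
-1.30901698935 0.425325404988 -1.03617915484
1.3090169994 0.425325401737 -1.03617914347
0.80901700083 -0.26286555829 -1.56191025722
0.809016997491 -1.11351636623 -1.03617914444
0.500000007636 0.688190958388 -1.56191025931
-0.80901698792 -0.262865556281 -1.56191026425
5.72550235339e-09 -0.850650809578 -1.56191026027
-0.809016991259 -1.11351636422 -1.03617915146
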