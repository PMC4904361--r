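# 37|pentagonal rotunda (J6)|Johnson
1.61803398955 -2.31849444285e-09 -0.556758179877
1.30901699514 0.951056513966 -0.556758184378
0.500000000748 1.53884176623 -0.556758188049
-0.499999999252 1.5388417662 -0.556758189488
-1.30901699361 0.951056513875 -0.556758188146
-1.61803398795 -2.43035165568e-09 -0.556758184535
-1.30901699354 -0.951056518715 -0.556758180034
-0.499999999145 -1.53884177098 -0.556758176363
0.500000000855 -1.53884177094 -0.556758174923
1.30901699521 -0.951056518624 -0.556758176266
-4.70592017995e-10 1.37638192172 0.293892620276
-0.500000001204 0.688190963714 0.819623734611
-1.30901699481 0.425325405384 0.293892622448
1.30901699394 0.425325405475 0.293892626216
0.809016993204 -0.262865552536 0.819623740551
0.80901699399 -1.11351636313 0.29389263206
0.499999998796 0.688190963748 0.81962373605
-0.809016995546 -0.262865552592 0.819623738222
-1.15032773893e-09 -0.850650804857 0.819623741893
-0.809016994759 -1.11351636319 0.293892629731
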