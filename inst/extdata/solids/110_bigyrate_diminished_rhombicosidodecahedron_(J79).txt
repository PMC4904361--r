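# 110|bigyrate diminished rhombicosidodecahedron (J79)|Johnson
-1.89442719188 -0.702146074727 -0.710343335605
-2.20344418518 -0.202146072838 0.0986736580152
-2.11803398951 0.659657324843 -0.401326344207
-2.11803398802 0.659657327274 0.598673655793
-1.80901699622 0.159657322954 -1.21034333783
-1.80901699232 0.159657329319 1.40769065092
-1.39442719122 -1.51116306822 -0.401326340008
-1.89442718947 -0.702146070793 0.907690653145
-1.61803399018 1.46867431859 -0.710343341295
-1.61803398777 1.46867432253 0.907690647455
-1.39442718973 -1.51116306579 0.598673659992
-1.30901699648 -0.649359672046 -1.51936033098
-1.30901699165 -0.649359664179 1.71670764652
-1.30901699688 0.968674316703 -1.51936033491
-1.30901699206 0.968674324571 1.71670764258
-1.30901699472 1.96867432064 0.0986736514038
-0.809016995812 -1.45837666554 -1.21034333538
-0.809016991909 -1.45837665918 1.40769065337
-0.809016996627 1.77769131196 -1.21034334325
-0.500000000105 -1.9583766635 -0.401326340254
-0.499999998614 -1.95837666107 0.598673659746
-0.500000002925 -0.340342678683 -2.01936033294
-0.499999996609 -0.340342668384 2.21670764456
-0.500000003177 0.659657321317 -2.01936033537
-0.499999996861 0.659657331616 2.21670764213
-0.500000001172 2.277691314 -0.401326350554
-2.26047536892e-09 -1.14935967218 -1.71034333734
3.13364305379e-09 -1.14935966338 1.90769065141
-2.91983930527e-09 1.46867431657 -1.71034334371
0.499999999895 -1.95837666325 -0.401326341745
0.500000001386 -1.95837666082 0.598673658255
0.361803395697 0.159657321326 -2.10477053206
0.500000003391 -0.340342668132 2.21670764307
0.861803395954 0.968674316578 -1.7957535404
0.500000003139 0.659657331868 2.21670764064
0.499999998828 2.27769131425 -0.401326352045
0.809016992938 -1.45837666514 -1.2103433378
0.809016996841 -1.45837665877 1.40769065095
0.809016992123 1.77769131236 -1.21034334566
1.30901699494 -1.64935966745 0.0986736562971
0.861803396361 -0.649359672172 -1.79575353647
1.3090169971 -0.649359663519 1.71670764262
1.67082039115 0.659657323623 -1.29575354086
1.30901699669 0.968674325231 1.71670763868
1.30901699403 1.9686743213 0.0986736475006
1.61803398798 -1.14935966934 -0.710343339754
1.61803399039 -1.14935966541 0.907690648996
1.61803398732 1.46867431941 -0.710343346119
1.61803398973 1.46867432334 0.90769064263
1.6708203914 -0.340342676377 -1.29575353842
1.80901699643 0.15965733023 1.40769064553
2.11803398824 -0.34034267409 -0.401326348092
2.11803398973 -0.340342671659 0.598673651908
2.11803398799 0.65965732591 -0.401326350523
2.11803398948 0.659657328341 0.598673649477
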