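# 109|metagyrate diminished rhombicosidodecahedron (J78)|Johnson
-2.27769131339 0.401326356277 -0.499999999337
-2.27769131317 0.401326355898 0.500000000663
-1.96867432147 -0.0986736448178 -1.30901699397
-1.96867432088 -0.0986736458095 1.30901699478
-1.7776913098 1.2103433485 -0.809016993518
-1.77769130943 1.21034334789 0.809016995232
-1.46867432521 -0.907690641342 -1.61803398876
-1.46867432448 -0.907690642568 1.61803398874
-1.46867431787 0.710343347407 -1.61803398815
-1.46867431714 0.710343346182 1.61803398935
-1.46867431297 1.71034334679 9.77307270719e-10
-0.968674328803 -1.7167076381 -1.30901699481
-0.968674328216 -1.71670763909 1.30901699394
-0.968674314133 1.5193603394 -1.30901699358
-0.968674313546 1.51936033841 1.30901699517
-0.659657336514 -2.21670763981 -0.500000000692
-0.65965733629 -2.21670764019 0.499999999308
-0.659657329541 -0.598673650446 -2.11803398883
-0.659657328591 -0.59867365205 2.11803398867
-0.659657325008 0.401326349554 -2.11803398845
-0.659657324058 0.40132634795 2.11803398905
-0.65965731731 2.01936033769 -0.499999999087
-0.659657317085 2.01936033731 0.500000000913
-0.15965733314 -1.4076906472 -1.80901699487
-0.159657332328 -1.40769064858 1.80901699388
-0.159657321271 1.21034334155 -1.80901699388
-0.159657320459 1.21034334017 1.80901699487
0.340342663486 -2.21670764434 -0.500000000916
0.34034266371 -2.21670764472 0.499999999084
0.202146071581 -0.0986736543204 -2.20344418546
0.340342671409 -0.598673656584 2.11803398845
0.702146075318 0.710343337671 -1.89442719089
0.340342675942 0.401326343416 2.11803398883
0.34034268269 2.01936033316 -0.499999999311
0.340342682915 2.01936033278 0.500000000689
0.649359659946 -1.71670764544 -1.30901699517
0.649359660534 -1.71670764643 1.30901699358
0.649359674617 1.51936033206 -1.30901699395
0.649359675204 1.51936033107 1.3090169948
1.14935965937 -1.90769065382 -9.80442001799e-10
0.702146067983 -0.907690651079 -1.8944271915
1.14935966427 -0.907690654437 1.61803398815
1.5111630684 0.401326339439 -1.39442719119
1.14935967161 0.710343334313 1.61803398876
1.14935967578 1.71034333493 3.90089092725e-10
1.45837665583 -1.40769065492 -0.809016995235
1.4583766562 -1.40769065553 0.809016993515
1.4583766677 1.21034333383 -0.809016994244
1.45837666807 1.21034333322 0.809016994506
1.51116306387 -0.598673660561 -1.39442719157
1.64935966787 -0.0986736622119 1.30901699397
1.95837665957 -0.598673662928 -0.500000000666
1.9583766598 -0.598673663306 0.499999999334
1.9583766641 0.401326337072 -0.500000000287
1.95837666433 0.401326336694 0.499999999713
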