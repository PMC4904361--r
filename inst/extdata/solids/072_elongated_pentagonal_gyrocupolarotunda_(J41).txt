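# 72|elongated pentagonal gyrocupolarotunda (J41)|Johnson
1.61803398962 -5.77894573344e-10 0.814471657791
1.30901699637 0.951056516082 0.814471656567
0.500000002691 1.53884176933 0.814471656475
-0.499999997309 1.53884177051 0.814471657549
-1.30901699238 0.951056519173 0.81447165938
-1.61803398788 3.24230081623e-09 0.814471661267
-1.30901699462 -0.951056513418 0.814471662491
-0.500000000942 -1.53884176667 0.814471662583
0.499999999058 -1.53884176785 0.814471661509
1.30901699413 -0.951056516508 0.814471659679
0.809016996125 0.262865557297 1.34020277035
2.44376485836e-09 0.850650810544 1.34020277026
-0.809016992625 0.262865559207 1.34020277209
-0.499999999373 -0.688190957453 1.34020277331
0.500000000627 -0.688190958634 1.34020277224
1.61803398855 -2.21355988722e-09 -0.185528342209
1.3090169953 0.951056514446 -0.185528343433
0.500000001617 1.53884176769 -0.185528343525
-0.499999998383 1.53884176887 -0.185528342451
-1.30901699345 0.951056517537 -0.18552834062
-1.61803398895 1.60663535889e-09 -0.185528338733
-1.3090169957 -0.951056515053 -0.185528337509
-0.500000002016 -1.5388417683 -0.185528337417
0.499999997984 -1.53884176948 -0.185528338491
1.30901699305 -0.951056518144 -0.185528340321
-0.809016994173 1.11351636367 -1.03617914978
-0.809016995742 0.26286555446 -1.5619102605
-1.30901699599 -0.425325404326 -1.03617914672
0.809016994576 1.11351636176 -1.03617915151
0.809016993008 0.26286555255 -1.56191026224
1.30901699276 -0.425325407416 -1.03617914953
-6.73514640631e-10 0.850650805797 -1.56191026233
-0.50000000249 -0.6881909622 -1.56191025928
0.49999999751 -0.688190963381 -1.56191026035
-2.73782902337e-09 -1.37638192217 -1.03617914657
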