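# 78|gyroelongated pentagonal cupolarotunda (J47)|Johnson
1.61803398957 1.16970353292e-09 0.735841374216
1.30901699504 0.951056517416 0.73584137338
0.500000000577 1.53884176958 0.735841373553
-0.499999999423 1.53884176942 0.735841374668
-1.30901699371 0.951056517001 0.735841376299
-1.61803398793 6.57053567581e-10 0.735841377824
-1.3090169934 -0.951056515589 0.73584137866
-0.499999998936 -1.53884176775 0.735841378488
0.500000001064 -1.5388417676 0.735841377373
1.30901699535 -0.951056515174 0.735841375742
0.80901699574 0.262865557754 1.26157248691
1.27164136822e-09 0.850650809918 1.26157248708
-0.80901699301 0.262865557497 1.26157248872
-0.499999998485 -0.688190958749 1.26157248955
0.500000001515 -0.68819095859 1.26157248844
1.53884176837 0.500000000087 -0.126555630175
0.951056515947 1.30901699437 -0.126555630524
-3.97408991464e-10 1.61803398859 -0.126555629848
-0.951056516644 1.30901699407 -0.126555628404
-1.53884176881 0.499999999599 -0.126555626744
-1.53884176865 -0.500000000401 -0.126555625503
-0.951056516229 -1.30901699468 -0.126555625154
1.15240890638e-10 -1.61803398891 -0.126555625831
0.951056516361 -1.30901699438 -0.126555627275
1.53884176853 -0.499999999913 -0.126555628934
-0.425325405473 1.30901699309 -0.977206437342
-0.68819096199 0.499999998025 -1.50293754816
-1.37638192156 -1.43102094351e-09 -0.977206434657
1.11351636319 0.809016993338 -0.977206438437
0.850650806677 -1.73079462937e-09 -1.50293754926
1.11351636345 -0.809016995412 -0.977206436428
0.262865554256 0.809016992551 -1.50293754961
-0.688190961832 -0.500000001975 -1.50293754692
0.262865554512 -0.809016996199 -1.5029375476
-0.425325405058 -1.30901699566 -0.977206434092
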