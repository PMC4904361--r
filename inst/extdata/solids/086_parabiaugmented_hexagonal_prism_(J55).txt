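# 86|parabiaugmented hexagonal prism (J55)|Johnson
1.00000000127 1.81777853609e-08 0.499999997468
0.499999985696 0.866025412973 0.499999998388
-0.500000014304 0.866025394995 0.50000000092
-0.999999998734 -1.77786782267e-08 0.500000002532
-0.499999983164 -0.866025412574 0.500000001612
0.500000016836 -0.866025394596 0.49999999908
0.999999998734 1.77786782142e-08 -0.500000002532
0.499999983164 0.866025412574 -0.500000001612
-0.500000016836 0.866025394596 -0.49999999908
-1.00000000127 -1.81777851969e-08 -0.499999997468
-0.499999985696 -0.866025412973 -0.499999998388
0.500000014304 -0.866025394995 -0.50000000092
1.36237244984 -0.786566067992 -3.13571052655e-09
-1.36237244984 0.786566067992 3.13571046604e-09
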