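# 56|gyroelongated pentagonal rotunda (J25)|Johnson
1.61803398886 5.14076421729e-09 -0.0837064513934
1.30901699146 0.951056520455 -0.0837064517656
0.499999995224 1.53884177018 -0.0837064528069
-0.500000004776 1.538841767 -0.0837064541196
-1.30901699729 0.951056512142 -0.0837064552022
-1.61803398864 -5.13487832023e-09 -0.0837064556413
-1.30901699125 -0.951056520449 -0.0837064552691
-0.499999995004 -1.53884177017 -0.0837064542278
0.500000004996 -1.538841767 -0.0837064529152
1.3090169975 -0.951056512136 -0.0837064518325
-5.37723210836e-09 1.37638192044 0.766944354883
-0.500000003882 0.688190958602 1.29267546632
-1.30901699673 0.425325399992 0.766944353131
1.30901699202 0.425325408306 0.766944356568
0.809016993513 -0.262865553536 1.29267546801
0.809016996904 -1.11351636187 0.766944355857
0.499999996118 0.688190961778 1.29267546763
-0.809016995237 -0.262865558674 1.29267546588
1.00426370387e-09 -0.850650808397 1.29267546692
-0.809016991846 -1.11351636701 0.766944353734
1.53884176824 0.50000000492 -0.946103455339
0.95105651338 1.30901699743 -0.946103456082
-3.89590510038e-09 1.61803398878 -0.94610345732
-0.95105651921 1.30901699139 -0.946103458579
-1.53884176893 0.499999995147 -0.946103459379
-1.53884176576 -0.500000004853 -0.946103459414
-0.951056510897 -1.30901699736 -0.946103458671
6.37973737776e-09 -1.61803398872 -0.946103457434
0.951056521694 -1.30901699132 -0.946103456174
1.53884177142 -0.49999999508 -0.946103455374
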