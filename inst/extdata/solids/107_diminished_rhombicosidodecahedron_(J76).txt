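# 107|diminished rhombicosidodecahedron (J76)|Johnson
-2.01936033324 -0.500000000542 -0.659657329841
-2.01936033501 -0.500000000348 0.340342670159
-2.01936033344 0.499999999458 -0.659657330035
-2.01936033522 0.499999999652 0.340342669965
-1.71034333753 -6.35889997215e-10 -1.46867432376
-1.71034334218 -1.27791952277e-10 1.14935966499
-1.51936033252 -1.30901699487 -0.968674323171
-1.5193603354 -1.30901699456 0.649359665579
-1.51936033306 1.30901699388 -0.968674323679
-1.51936033593 1.30901699419 0.64935966507
-1.21034333948 -1.80901699465 -0.159657328151
-1.21034333681 -0.809016994968 -1.77769131709
-1.21034334256 -0.80901699434 1.45837666041
-1.21034333715 0.809016993782 -1.77769131741
-1.21034334289 0.80901699441 1.45837666009
-1.21034334022 1.8090169941 -0.159657328853
-0.710343337196 -1.61803398918 -1.46867432167
-0.710343341845 -1.61803398867 1.14935966708
-0.71034333786 1.61803398832 -1.4686743223
-0.710343342509 1.61803398883 1.14935966645
-0.401326344155 -2.11803398896 -0.659657326654
-0.401326345931 -2.11803398877 0.340342673346
-0.401326341614 -0.500000000524 -2.27769131572
-0.401326349137 -0.499999999702 1.95837666178
-0.401326341819 0.499999999476 -2.27769131591
-0.401326349342 0.500000000298 1.95837666159
-0.401326345024 2.11803398854 -0.659657327476
-0.4013263468 2.11803398873 0.340342672524
0.0986736580032 -1.30901699474 -1.9686743203
0.0986736515781 -1.30901699403 1.64935966845
0.0986736574662 1.30901699401 -1.96867432081
0.0986736510411 1.30901699472 1.64935966794
0.598673655845 -2.11803398876 -0.659657324878
0.598673654069 -2.11803398856 0.340342675122
0.598673650863 -0.499999999497 1.95837666356
0.598673650658 0.500000000503 1.95837666336
0.598673654976 2.11803398874 -0.6596573257
0.5986736532 2.11803398894 0.3403426743
0.907690651554 -1.61803398885 -1.4686743188
0.907690646904 -1.61803398834 1.14935966995
0.90769065089 1.61803398865 -1.46867431943
0.907690646241 1.61803398916 1.14935966932
1.40769064927 -1.80901699412 -0.159657323501
1.40769064619 -0.809016993803 1.45837666505
1.40769064586 0.809016994947 1.45837666474
1.40769064853 1.80901699463 -0.159657324203
1.71670764498 -1.30901699421 -0.968674317425
1.7167076421 -1.3090169939 0.649359671325
1.71670764444 1.30901699454 -0.968674317933
1.71670764157 1.30901699485 0.649359670817
1.90769064657 6.14401878578e-10 1.14935967141
2.21670764426 -0.499999999673 -0.659657322319
2.21670764249 -0.499999999479 0.340342677681
2.21670764406 0.500000000327 -0.659657322513
2.21670764228 0.500000000521 0.340342677487
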