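# 34|triangular cupola (J3)|Johnson
0.999999999469 1.12150695164e-08 -0.272165528928
0.499999990886 0.866025410044 -0.272165523802
-0.500000009114 0.866025400133 -0.272165521849
-1.00000000053 -8.60639547833e-09 -0.272165525023
-0.499999991948 -0.866025407435 -0.27216553015
0.500000008052 -0.866025397525 -0.272165532103
0.499999998202 0.288675136942 0.544331054359
-0.500000001798 0.288675127031 0.544331056312
6.78481217213e-09 -0.577350271798 0.544331051185
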