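# 36|pentagonal cupola (J5)|Johnson
1.6180339879 2.06942763413e-09 -0.175243711877
1.30901699328 0.951056518286 -0.175243701384
0.49999999876 1.53884177037 -0.175243691905
-0.50000000124 1.53884177012 -0.175243687062
-1.30901699547 0.95105651762 -0.175243688703
-1.6180339896 1.24587553725e-09 -0.175243696203
-1.30901699498 -0.951056514971 -0.175243706696
-0.500000000457 -1.53884176706 -0.175243716174
0.499999999543 -1.5388417668 -0.175243721018
1.30901699377 -0.951056514304 -0.175243719376
0.809016996006 0.26286555295 0.350487406647
1.48113511737e-09 0.850650805037 0.350487416126
-0.809016992744 0.262865552538 0.350487414484
-0.499999998127 -0.688190963678 0.350487403992
0.500000001873 -0.688190963424 0.350487399148
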