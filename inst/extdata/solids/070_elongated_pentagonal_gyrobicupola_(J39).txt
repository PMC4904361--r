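# 70|elongated pentagonal gyrobicupola (J39)|Johnson
1.61803399157 8.05277921069e-09 0.49999999088
1.30901699473 0.951056523548 0.49999998527
0.499999998836 1.53884177375 0.499999985286
-0.500000001164 1.53884177116 0.499999990923
-1.30901699402 0.951056516772 0.500000000027
-1.61803398593 -3.22694801847e-10 0.50000000912
-1.3090169891 -0.951056515818 0.50000001473
-0.499999993199 -1.53884176602 0.500000014714
0.500000006801 -1.53884176343 0.500000009077
1.30901699965 -0.951056509042 0.499999999973
0.809016999476 0.262865566082 1.02573110553
3.57999279164e-09 0.850650816281 1.02573110554
-0.809016989274 0.262865561895 1.02573111465
-0.499999992437 -0.688190953601 1.02573112026
0.500000007563 -0.688190951013 1.02573111462
1.61803398593 3.22694887455e-10 -0.50000000912
1.3090169891 0.951056515818 -0.50000001473
0.499999993199 1.53884176602 -0.500000014714
-0.500000006801 1.53884176343 -0.500000009077
-1.30901699965 0.951056509042 -0.499999999973
-1.61803399157 -8.05277914604e-09 -0.49999999088
-1.30901699473 -0.951056523548 -0.49999998527
-0.499999998836 -1.53884177375 -0.499999985286
0.500000001164 -1.53884177116 -0.499999990923
1.30901699402 -0.951056516772 -0.500000000027
0.499999992437 0.688190953601 -1.02573112026
-0.500000007563 0.688190951013 -1.02573111462
-0.809016999476 -0.262865566082 -1.02573110553
-3.57999287154e-09 -0.850650816281 -1.02573110554
0.809016989274 -0.262865561895 -1.02573111465
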