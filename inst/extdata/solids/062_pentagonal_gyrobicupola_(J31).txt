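# 62|pentagonal gyrobicupola (J31)|Johnson
1.61803398875 -2.51833742461e-09 4.65332618707e-09
1.30901699586 0.951056514258 2.29650357122e-09
0.500000002395 1.53884176781 -9.37505447529e-10
-0.499999997605 1.53884176937 -3.81341894252e-09
-1.30901699289 0.951056518333 -5.23273600637e-09
-1.61803398875 2.51833723545e-09 -4.6533258781e-09
-1.30901699586 -0.951056514258 -2.29650356645e-09
-0.500000002395 -1.53884176781 9.3750542919e-10
0.499999997605 -1.53884176937 3.81341880807e-09
1.30901699289 -0.951056518333 5.23273608152e-09
0.809016993272 0.262865555612 0.52573111404
-1.87988915156e-10 0.850650809164 0.525731110806
-0.809016995478 0.26286555813 0.525731109387
-0.500000002583 -0.688190958646 0.525731111744
0.499999997417 -0.688190960202 0.525731114619
0.500000002583 0.688190958646 -0.525731111744
-0.499999997417 0.688190960202 -0.525731114619
-0.809016993272 -0.262865555612 -0.52573111404
1.879889954e-10 -0.850650809164 -0.525731110806
0.809016995478 -0.26286555813 -0.525731109387
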