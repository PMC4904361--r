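# 4|dodecahedron|Platonic
-0.809016994375 -0.809016994375 -0.809016994375
-0.809016994375 -0.809016994375 0.809016994375
-0.809016994375 0.809016994375 -0.809016994375
-0.809016994375 0.809016994375 0.809016994375
0.809016994375 -0.809016994375 -0.809016994375
0.809016994375 -0.809016994375 0.809016994375
0.809016994375 0.809016994375 -0.809016994375
0.809016994375 0.809016994375 0.809016994375
2.22044604925e-17 -0.5 -1.30901699437
-1.30901699437 0 -0.5
-0.5 -1.30901699437 4.02455846427e-19
2.22044604925e-17 -0.5 1.30901699437
1.30901699437 0 -0.5
-0.5 1.30901699437 4.02455846427e-19
2.22044604925e-17 0.5 -1.30901699437
-1.30901699437 0 0.5
0.5 -1.30901699437 4.02455846427e-19
2.22044604925e-17 0.5 1.30901699437
1.30901699437 0 0.5
0.5 1.30901699437 4.02455846427e-19
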