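# 90|parabiaugmented dodecahedron (J59)|Johnson
-0.809016994375 -0.809016994375 -0.809016994375
-0.809016994375 -0.809016994375 0.809016994375
-0.809016994375 0.809016994375 -0.809016994375
-0.809016994375 0.809016994375 0.809016994375
0.809016994375 -0.809016994375 -0.809016994375
0.809016994375 -0.809016994375 0.809016994375
0.809016994375 0.809016994375 -0.809016994375
0.809016994375 0.809016994375 0.809016994375
1.16068770756e-17 -0.5 -1.30901699437
-1.30901699437 -1.26769448934e-17 -0.5
-0.5 -1.30901699437 -5.55111512313e-18
1.16068770756e-17 -0.5 1.30901699437
1.30901699437 -1.26769448934e-17 -0.5
-0.5 1.30901699437 -5.55111512313e-18
1.16068770756e-17 0.5 -1.30901699437
-1.30901699437 -1.26769448934e-17 0.5
0.5 -1.30901699437 -5.55111512313e-18
1.16068770756e-17 0.5 1.30901699437
1.30901699437 -1.26769448934e-17 0.5
0.5 1.30901699437 -5.55111512313e-18
0.861803398875 4.75744606397e-18 -1.394427191
-0.861803398875 4.75744606397e-18 1.394427191
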