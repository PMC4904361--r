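# 13|icosidodecahedron|Archimedean
-0.809016994375 -0.5 -1.30901699437
-0.5 -1.30901699437 -0.809016994375
0.809016994375 -0.5 -1.30901699437
0 8.881784197e-17 -1.61803398875
0.5 -1.30901699437 -0.809016994375
-1.30901699437 -0.809016994375 -0.5
-1.30901699437 0.809016994375 -0.5
-0.809016994375 0.5 -1.30901699437
-1.61803398875 8.881784197e-17 8.881784197e-17
-0.5 -1.30901699437 0.809016994375
-1.30901699437 -0.809016994375 0.5
0 -1.61803398875 8.881784197e-17
-0.809016994375 -0.5 1.30901699437
0.5 -1.30901699437 0.809016994375
0 8.881784197e-17 1.61803398875
0.809016994375 -0.5 1.30901699437
0.809016994375 0.5 -1.30901699437
1.30901699437 -0.809016994375 -0.5
1.61803398875 8.881784197e-17 8.881784197e-17
1.30901699437 0.809016994375 -0.5
-0.5 1.30901699437 -0.809016994375
-1.30901699437 0.809016994375 0.5
-0.5 1.30901699437 0.809016994375
0 1.61803398875 8.881784197e-17
0.5 1.30901699437 -0.809016994375
-0.809016994375 0.5 1.30901699437
1.30901699437 -0.809016994375 0.5
0.809016994375 0.5 1.30901699437
0.5 1.30901699437 0.809016994375
1.30901699437 0.809016994375 0.5
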