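# 47|elongated pentagonal bipyramid (J16)|Johnson
0.850650808352 -2.55068599986e-17 0.5
0.26286555606 0.809016994375 0.5
-0.688190960236 0.5 0.5
-0.688190960236 -0.5 0.5
0.26286555606 -0.809016994375 0.5
2.22301600996e-17 -2.55068599986e-17 1.02573111212
0.850650808352 -2.55068599986e-17 -0.5
0.26286555606 0.809016994375 -0.5
-0.688190960236 0.5 -0.5
-0.688190960236 -0.5 -0.5
0.26286555606 -0.809016994375 -0.5
2.22301600996e-17 -2.55068599986e-17 -1.02573111212
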