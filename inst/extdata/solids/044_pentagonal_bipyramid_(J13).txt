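# 44|pentagonal bipyramid (J13)|Johnson
0.850650808352 -3.52811398496e-17 0
0.26286555606 0.809016994375 0
-0.688190960236 0.5 0
-0.688190960236 -0.5 0
0.26286555606 -0.809016994375 0
2.58944145685e-18 -3.52811398496e-17 0.525731112119
2.58944145685e-18 -3.52811398496e-17 -0.525731112119
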