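# 45|elongated triangular bipyramid (J14)|Johnson
0.57735026919 -2.94902990916e-17 0.5
-0.288675134595 0.5 0.5
-0.288675134595 -0.5 0.5
3.95733792957e-17 -2.94902990916e-17 1.31649658093
0.57735026919 -2.94902990916e-17 -0.5
-0.288675134595 0.5 -0.5
-0.288675134595 -0.5 -0.5
3.95733792957e-17 -2.94902990916e-17 -1.31649658093
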