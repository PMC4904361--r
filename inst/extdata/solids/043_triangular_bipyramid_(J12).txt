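# 43|triangular bipyramid (J12)|Johnson
0.57735026919 -4.70734562441e-17 0
-0.288675134595 0.5 0
-0.288675134595 -0.5 0
2.975397706e-17 -4.70734562441e-17 0.816496580928
2.975397706e-17 -4.70734562441e-17 -0.816496580928
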