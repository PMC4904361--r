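# 82|triaugmented triangular prism (J51)|Johnson
0.57735026919 -7.29560597746e-17 0.5
-0.288675134595 0.5 0.5
-0.288675134595 -0.5 0.5
0.57735026919 -7.29560597746e-17 -0.5
-0.288675134595 0.5 -0.5
-0.288675134595 -0.5 -0.5
0.497890957891 0.862372435696 4.52313084107e-17
0.497890957891 -0.862372435696 -1.02798428206e-17
-0.995781915781 3.12832422958e-16 -1.02798428206e-17
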