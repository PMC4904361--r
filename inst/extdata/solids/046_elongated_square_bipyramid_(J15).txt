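# 46|elongated square bipyramid (J15)|Johnson
0.707106781187 -2.68673971959e-17 0.5
6.21132073843e-17 0.707106781187 0.5
-0.707106781187 5.97282084276e-17 0.5
-1.11078003863e-16 -0.707106781187 0.5
1.88154045726e-17 -2.68673971959e-17 1.20710678119
0.707106781187 -2.68673971959e-17 -0.5
6.21132073843e-17 0.707106781187 -0.5
-0.707106781187 5.97282084276e-17 -0.5
-1.11078003863e-16 -0.707106781187 -0.5
1.88154045726e-17 -2.68673971959e-17 -1.20710678119
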