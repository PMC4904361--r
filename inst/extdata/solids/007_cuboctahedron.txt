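# 7|cuboctahedron|Archimedean
-0.707106781187 -0.707106781187 0
-0.707106781187 1.85037170771e-17 -0.707106781187
1.85037170771e-17 -0.707106781187 -0.707106781187
-0.707106781187 1.85037170771e-17 0.707106781187
1.85037170771e-17 -0.707106781187 0.707106781187
-0.707106781187 0.707106781187 0
1.85037170771e-17 0.707106781187 -0.707106781187
1.85037170771e-17 0.707106781187 0.707106781187
0.707106781187 -0.707106781187 0
0.707106781187 1.85037170771e-17 -0.707106781187
0.707106781187 1.85037170771e-17 0.707106781187
0.707106781187 0.707106781187 0
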