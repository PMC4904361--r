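# 20|rhombic dodecahedron|Catalan
-0.57735026919 0.57735026919 -0.57735026919
-0.57735026919 -0.57735026919 -0.57735026919
-0.57735026919 -0.57735026919 0.57735026919
0.57735026919 -0.57735026919 -0.57735026919
0.57735026919 0.57735026919 -0.57735026919
0.57735026919 -0.57735026919 0.57735026919
-0.57735026919 0.57735026919 0.57735026919
0.57735026919 0.57735026919 0.57735026919
-1.15470053838 0 1.58603289232e-17
1.58603289232e-17 -1.15470053838 1.58603289232e-17
1.58603289232e-17 0 -1.15470053838
1.15470053838 0 1.58603289232e-17
1.58603289232e-17 1.15470053838 1.58603289232e-17
1.58603289232e-17 0 1.15470053838
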