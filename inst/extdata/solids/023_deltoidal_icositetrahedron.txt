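# 23|deltoidal icositetrahedron|Catalan
-0.805863548229 0.805863548229 0.805863548229
-0.805863548229 -0.805863548229 -0.805863548229
0.805863548229 0.805863548229 0.805863548229
-0.805863548229 0.805863548229 -0.805863548229
0.805863548229 0.805863548229 -0.805863548229
-0.805863548229 -0.805863548229 0.805863548229
0.805863548229 -0.805863548229 -0.805863548229
0.805863548229 -0.805863548229 0.805863548229
-1.47346277043 -3.416070845e-17 0
-1.04189551679 1.04189551679 0
0 -3.416070845e-17 1.47346277043
-1.04189551679 -3.416070845e-17 1.04189551679
0 1.04189551679 1.04189551679
1.04189551679 -3.416070845e-17 -1.04189551679
1.47346277043 -3.416070845e-17 0
1.04189551679 -3.416070845e-17 1.04189551679
-1.04189551679 -3.416070845e-17 -1.04189551679
0 -3.416070845e-17 -1.47346277043
1.04189551679 1.04189551679 0
0 1.04189551679 -1.04189551679
0 1.47346277043 0
-1.04189551679 -1.04189551679 -0
0 -1.04189551679 -1.04189551679
0 -1.04189551679 1.04189551679
0 -1.47346277043 0
1.04189551679 -1.04189551679 0
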