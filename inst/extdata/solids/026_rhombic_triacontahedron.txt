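# 26|rhombic triacontahedron|Catalan
2.77555756156e-17 -1.37638192047 -0.525731112119
0.525731112119 4.16333634234e-17 1.37638192047
-1.37638192047 -0.525731112119 -4.21515225212e-17
-0.850650808352 -0.850650808352 -0.850650808352
-0.850650808352 -0.850650808352 0.850650808352
0.525731112119 4.16333634234e-17 -1.37638192047
0.850650808352 -0.850650808352 -0.850650808352
1.37638192047 -0.525731112119 -4.21515225212e-17
0.850650808352 -0.850650808352 0.850650808352
2.77555756156e-17 -1.37638192047 0.525731112119
-0.525731112119 4.16333634234e-17 1.37638192047
2.77555756156e-17 1.37638192047 -0.525731112119
0.850650808352 0.850650808352 0.850650808352
1.37638192047 0.525731112119 -4.21515225212e-17
0.850650808352 0.850650808352 -0.850650808352
-0.525731112119 4.16333634234e-17 -1.37638192047
-0.850650808352 0.850650808352 0.850650808352
2.77555756156e-17 1.37638192047 0.525731112119
-1.37638192047 0.525731112119 -4.21515225212e-17
-0.850650808352 0.850650808352 -0.850650808352
2.77555756156e-17 -0.850650808352 -1.37638192047
-0.850650808352 -1.37638192047 -4.21515225212e-17
1.37638192047 4.16333634234e-17 0.850650808352
0.850650808352 -1.37638192047 -4.21515225212e-17
-3.50009269724e-16 -0.850650808352 1.37638192047
-1.37638192047 2.30515786093e-16 0.850650808352
0.850650808352 1.37638192047 -4.21515225212e-17
1.37638192047 -3.36131481916e-16 -0.850650808352
2.16637998285e-16 0.850650808352 -1.37638192047
-1.61126847054e-16 0.850650808352 1.37638192047
-1.37638192047 4.16333634234e-17 -0.850650808352
-0.850650808352 1.37638192047 -1.36592733856e-16
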