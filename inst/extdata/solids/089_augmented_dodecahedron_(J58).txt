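# 89|augmented dodecahedron (J58)|Johnson
-0.850055251464 -0.809016994375 -0.742615699565
-0.850055251464 -0.809016994375 0.875418289184
-0.850055251464 0.809016994375 -0.742615699565
-0.850055251464 0.809016994375 0.875418289184
0.767978737286 -0.809016994375 -0.742615699565
0.767978737286 -0.809016994375 0.875418289184
0.767978737286 0.809016994375 -0.742615699565
0.767978737286 0.809016994375 0.875418289184
-0.0410382570893 -0.5 -1.24261569957
-1.35005525146 -2.20344825651e-17 -0.43359870519
-0.541038257089 -1.30901699437 0.0664012948095
-0.0410382570893 -0.5 1.37541828918
1.26797873729 -2.20344825651e-17 -0.43359870519
-0.541038257089 1.30901699437 0.0664012948095
-0.0410382570893 0.5 -1.24261569957
-1.35005525146 -2.20344825651e-17 0.56640129481
0.458961742911 -1.30901699437 0.0664012948095
-0.0410382570893 0.5 1.37541828918
1.26797873729 -2.20344825651e-17 0.56640129481
0.458961742911 1.30901699437 0.0664012948095
0.820765141786 -4.60009160775e-18 -1.32802589619
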