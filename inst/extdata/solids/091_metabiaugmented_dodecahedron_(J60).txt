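# 91|metabiaugmented dodecahedron (J60)|Johnson
-0.78480682219 -0.769844112245 -0.745633940419
-0.784806822774 -0.769844112029 0.872400048331
-0.784806821237 0.848189876505 -0.745633940635
-0.784806821821 0.84818987672 0.872400048115
0.83322716656 -0.769844113198 -0.745633939836
0.833227165976 -0.769844112983 0.872400048914
0.833227167513 0.848189875552 -0.745633940051
0.833227166929 0.848189875767 0.872400048699
0.0242101725472 -0.460827118413 -1.24563394017
-1.28480682183 0.0391728824659 -0.436616946332
-0.475789828402 -1.26984411232 0.0633830541337
0.0242101716027 -0.460827118065 1.37240004858
1.33322716692 0.0391728809235 -0.436616945388
-0.475789826859 1.34818987643 0.0633830537853
0.0242101731364 0.539172881587 -1.2456339403
-1.28480682219 0.039172882599 0.563383053668
0.524210171598 -1.26984411291 0.0633830544945
0.0242101721918 0.539172881935 1.37240004845
1.33322716656 0.0391728810565 0.563383054612
0.524210173141 1.34818987584 0.0633830541461
0.886013571748 0.0391728810679 -1.33104413655
-1.37021701914 -0.822630516292 0.0633830537515
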