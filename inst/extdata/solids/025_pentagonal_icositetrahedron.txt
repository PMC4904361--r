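# 25|pentagonal icositetrahedron|Catalan
-1.06795805677 1.47696097081 -0.315686332396
-1.06795808114 1.06795870136 -1.06795867425
-1.47696050259 0.315686442141 -1.06795867187
1.06795808114 -1.06795870136 1.06795867425
-0.315685667035 1.06795847473 -1.4769608108
0.315685604082 -1.47696072212 1.06795861598
-0.315686567855 -1.06795830659 1.47696073984
-1.06795889002 -1.06795813254 1.06795843418
1.06795812773 -1.47696101139 -0.315685902493
1.4769603868 -1.06795885862 0.31568635208
-0.315685844145 1.47696085939 1.06795835518
-1.47696091079 -0.315685655479 1.06795833987
-1.47696045776 1.0679588992 0.31568588281
-1.06795856751 0.315686496774 1.47696056637
-1.0679583212 1.06795883862 1.06795829691
-1.06795840365 -0.315685927956 -1.47696080643
1.47696067073 0.315685792748 1.06795863129
1.06795823551 -0.315686306934 1.47696084701
0.315686235854 1.06795849643 1.47696067353
1.06795864996 1.06795826981 1.06795853698
1.06795889002 1.06795813254 -1.06795843418
1.47696102658 1.06795807196 -0.315686020079
0.315686630808 1.47696055398 -1.06795854502
1.06795884343 1.47696044257 0.315686142556
1.06795873565 0.315685738116 -1.47696060694
1.47696074265 -0.315686579411 -1.06795829929
1.0679583212 -1.06795883862 -1.06795829691
0.315685999036 -1.06795866457 -1.47696060257
-1.06795891439 -1.47696040199 0.315686092333
-1.47696095562 -1.06795811254 -0.315686214811
-1.06795864996 -1.06795826981 -1.06795853698
-0.315686390745 -1.47696069125 -1.06795842614
1.96428189765 -5.23110324537e-07 2.20772347638e-07
-1.96428189765 5.23110324715e-07 -2.20772347395e-07
-2.20772313703e-07 1.26238747484e-07 1.96428189765
5.23110338807e-07 1.96428189765 -1.26238688585e-07
2.20772313779e-07 -1.26238747536e-07 -1.96428189765
-5.23110338916e-07 -1.96428189765 1.2623868911e-07
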