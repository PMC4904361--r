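# 64|pentagonal gyrocupolarotunda (J33)|Johnson
1.61803398649 -1.03146016222e-08 0.340260334086
1.30901700092 0.95105650884 0.340260319017
0.500000011979 1.53884176862 0.340260305599
-0.499999988021 1.53884177787 0.340260298958
-1.30901698783 0.951056533065 0.340260301631
-1.61803399101 1.96287940835e-08 0.340260312596
-1.30901700543 -0.951056499526 0.340260327665
-0.500000016499 -1.5388417593 0.340260341082
0.499999983501 -1.53884176856 0.340260347723
1.30901698332 -0.95105652375 0.340260345051
0.809016991056 0.262865560426 0.865991437235
2.1201799801e-09 0.850650820205 0.865991423817
-0.809016997694 0.262865575398 0.86599142649
-0.500000012119 -0.688190943756 0.865991441559
0.499999987881 -0.688190953009 0.8659914482
-0.809016980682 1.11351636491 -0.510390505624
-0.809016985062 0.262865549364 -1.0361216061
-1.30901699492 -0.425325399049 -0.510390487883
0.809017008068 1.11351634994 -0.510390494879
0.809017003688 0.262865534392 -1.03612159536
1.30901699383 -0.425325423274 -0.510390470497
1.47518013687e-08 0.850650794171 -1.03612160877
-0.499999999487 -0.68819096979 -1.03612159103
0.500000000513 -0.688190979043 -1.03612158439
-9.34626730126e-09 -1.37638192746 -0.510390466173
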