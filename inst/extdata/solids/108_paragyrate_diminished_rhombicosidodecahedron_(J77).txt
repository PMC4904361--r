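# 108|paragyrate diminished rhombicosidodecahedron (J77)|Johnson
-2.2167076428 -0.499999998315 -0.340342677366
-2.21670764399 -0.500000000475 0.659657322634
-2.21670764237 0.500000001685 -0.340342675206
-2.21670764356 0.499999999525 0.659657324794
-1.90769064725 3.29934940754e-09 -1.14935967029
-1.71670764278 -1.30901699224 -0.649359672893
-1.7167076447 -1.30901699573 0.968674315857
-1.71670764165 1.30901699651 -0.649359667239
-1.71670764358 1.30901699302 0.968674321511
-1.40769064958 -1.80901699412 0.15965732077
-1.40769064722 -0.809016990622 -1.45837666582
-1.40769064653 0.809016998127 -1.45837666233
-1.40769064803 1.80901699463 0.159657328584
-0.907690647939 -1.61803398588 -1.1493596726
-0.907690651055 -1.61803399153 1.46867431615
-0.907690646553 1.61803399162 -1.14935966561
-0.907690649668 1.61803398597 1.46867432314
-0.598673654741 -2.11803398776 -0.340342678934
-0.598673655931 -2.11803398992 0.659657321066
-0.598673652122 -0.499999995514 -1.95837666419
-0.598673651694 0.500000004486 -1.95837666203
-0.598673652926 2.11803398974 -0.340342669786
-0.598673654116 2.11803398758 0.659657330214
-0.0986736528364 -1.30901699077 -1.64935967097
-0.0986736571424 -1.30901699858 1.96867431778
-0.0986736517149 1.30901699798 -1.64935966531
-0.0986736560209 1.30901699017 1.96867432344
0.401326345259 -2.11803398819 -0.340342677744
0.401326344069 -2.11803399035 0.659657322256
0.263129747069 4.30099836076e-09 -2.04378685871
0.401326342836 -0.500000005091 2.2776913145
0.763129747048 0.809016997794 -1.73476986199
0.401326343265 0.499999994909 2.27769131666
0.401326347074 2.11803398931 -0.340342668596
0.401326345884 2.11803398715 0.659657331404
0.710343340811 -1.61803398657 -1.14935967067
0.710343337695 -1.61803399223 1.46867431808
0.710343342197 1.61803399093 -1.14935966368
0.710343339081 1.61803398527 1.46867432507
1.21034333917 -1.80901699524 0.159657323886
0.763129746354 -0.809016990955 -1.73476986549
1.21034333767 -0.809016998732 1.7776913148
1.5721467407 0.500000001993 -1.2347698617
1.21034333837 0.809016990017 1.77769131829
1.21034334072 1.80901699351 0.159657331699
1.51936033472 -1.30901699362 -0.649359669041
1.5193603328 -1.30901699712 0.968674319709
1.51936033584 1.30901699513 -0.649359663387
1.51936033392 1.30901699163 0.968674325362
1.57214674027 -0.499999998007 -1.23476986386
1.71034333839 -3.90439478125e-09 1.46867432276
2.0193603347 -0.50000000013 -0.340342672324
2.01936033351 -0.50000000229 0.659657327676
2.01936033513 0.49999999987 -0.340342670165
2.01936033394 0.49999999771 0.659657329835
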