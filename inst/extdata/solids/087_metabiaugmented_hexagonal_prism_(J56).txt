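# 87|metabiaugmented hexagonal prism (J56)|Johnson
1.00000000016 0.112366584407 0.49999999974
0.50000000051 0.978391988395 0.499999999548
-0.49999999949 0.978391988804 0.499999999769
-0.999999999844 0.112366585224 0.500000000182
-0.500000000197 -0.753658818765 0.500000000373
0.499999999803 -0.753658819174 0.500000000152
0.999999999935 0.112366584058 -0.50000000026
0.500000000289 0.978391988047 -0.500000000452
-0.499999999711 0.978391988455 -0.500000000231
-1.00000000006 0.112366584875 -0.499999999818
-0.500000000418 -0.753658819114 -0.499999999627
0.499999999582 -0.753658819522 -0.499999999848
1.36237243542 -0.674199508401 -6.6000269023e-11
-1.36237243597 -0.674199507288 5.36211353792e-10
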