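# 51|elongated pentagonal cupola (J20)|Johnson
1.61803398882 5.43080325874e-09 0.294853777178
1.30901699111 0.951056520641 0.294853778067
0.499999994668 1.53884177009 0.294853778769
-0.500000005332 1.53884176658 0.294853779014
-1.30901699764 0.951056511446 0.294853778711
-1.61803398868 -5.93485691099e-09 0.294853777974
-1.30901699096 -0.951056521145 0.294853777085
-0.499999994523 -1.5388417706 0.294853776384
0.500000005477 -1.53884176708 0.294853776138
1.30901699779 -0.95105651195 0.294853776441
0.809016993654 0.2628655582 0.820584889721
-2.78582819114e-09 0.850650807651 0.820584890422
-0.809016995096 0.262865552517 0.820584890119
-0.499999997381 -0.688190962693 0.82058488923
0.500000002619 -0.688190959181 0.820584888984
1.61803398858 6.28555518157e-09 -0.705146222822
1.30901699086 0.951056521495 -0.705146221933
0.499999994422 1.53884177095 -0.705146221231
-0.500000005578 1.53884176743 -0.705146220986
-1.30901699789 0.9510565123 -0.705146221289
-1.61803398892 -5.08010505758e-09 -0.705146222026
-1.30901699121 -0.95105652029 -0.705146222915
-0.499999994769 -1.53884176974 -0.705146223616
0.500000005231 -1.53884176623 -0.705146223862
1.30901699754 -0.951056511095 -0.705146223559
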