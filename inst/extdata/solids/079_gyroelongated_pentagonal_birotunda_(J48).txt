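# 79|gyroelongated pentagonal birotunda (J48)|Johnson
1.61803398801 3.97679348887e-10 0.431198504699
1.30901699404 0.951056516825 0.431198501763
0.499999999922 1.53884176946 0.431198498891
-0.500000000078 1.53884176989 0.431198497179
-1.30901699471 0.951056517948 0.431198497282
-1.61803398949 1.78493092263e-09 0.43119849916
-1.30901699552 -0.951056514643 0.431198502096
-0.500000001398 -1.53884176728 0.431198504969
0.499999998602 -1.53884176771 0.43119850668
1.30901699323 -0.951056515765 0.431198506577
-1.60399197696e-09 1.37638192372 1.2818493068
-0.500000002799 0.688190965025 1.8075804198
-1.30901699639 0.425325407981 1.28184930696
1.30901699236 0.425325406859 1.28184931145
0.809016991168 -0.262865551832 1.80758042445
0.809016991704 -1.11351636151 1.28184931448
0.499999997201 0.688190964596 1.80758042151
-0.809016997582 -0.262865551138 1.80758042168
-3.45853230506e-09 -0.850650803777 1.80758042455
-0.809016997046 -1.11351636082 1.28184931172
1.53884176954 0.499999998249 -0.431198500561
0.951056517594 1.30901699288 -0.431198503615
1.43166920823e-09 1.61803398766 -0.431198506025
-0.951056514996 1.30901699369 -0.431198506871
-1.53884176764 0.499999999568 -0.431198505829
-1.53884176806 -0.500000000432 -0.431198503298
-0.951056516118 -1.30901699506 -0.431198500245
4.44175131001e-11 -1.61803398984 -0.431198497835
0.951056516472 -1.30901699587 -0.431198496989
1.53884176911 -0.500000001751 -0.43119849803
-0.425325401421 1.30901699131 -1.28184931432
-0.688190956927 0.49999999572 -1.80758042484
-1.37638191828 -2.6541540877e-09 -1.28184931264
1.11351636695 0.809016990653 -1.28184931042
0.850650811446 -4.93940240285e-09 -1.80758042094
1.11351636626 -0.809016998096 -1.28184930633
0.2628655595 0.809016989688 -1.807580424
-0.688190957356 -0.50000000428 -1.80758042231
0.262865558807 -0.809016999062 -1.8075804199
-0.425325402543 -1.30901699744 -1.2818493077
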