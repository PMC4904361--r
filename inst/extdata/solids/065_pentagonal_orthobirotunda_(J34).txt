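# 65|pentagonal orthobirotunda (J34)|Johnson
1.61803398875 -2.57485604608e-10 1.74258597871e-09
1.30901699453 0.951056516087 1.63622224935e-09
0.500000000245 1.53884176851 9.04877243032e-10
-0.499999999755 1.53884176867 -1.72100138397e-10
-1.30901699422 0.951056516503 -1.18334116482e-09
-1.61803398875 2.57485375823e-10 -1.74258615185e-09
-1.30901699453 -0.951056516087 -1.63622244661e-09
-0.500000000245 -1.53884176851 -9.04877395164e-10
0.499999999755 -1.53884176867 1.72099984061e-10
1.30901699422 -0.951056516503 1.18334101644e-09
-6.97101312441e-10 1.37638192027 0.85065080868
-0.500000001373 0.688190959987 1.3763819201
-1.30901699522 0.425325404182 0.850650807044
1.30901699353 0.425325403765 0.850650809863
0.809016992851 -0.262865556516 1.37638192128
0.809016993282 -1.11351636474 0.850650808958
0.499999998627 0.688190959828 1.37638192117
-0.809016995899 -0.262865556259 1.37638191954
-1.61770041397e-09 -0.85065080868 1.37638192027
-0.809016995468 -1.11351636449 0.850650807216
1.13516205427e-09 1.37638192067 -0.850650808024
-0.499999998408 0.688190960643 -1.37638192085
-1.30901699339 0.425325404587 -0.850650809661
1.30901699536 0.42532540417 -0.850650806841
0.809016995815 -0.262865555861 -1.37638191966
0.809016995114 -1.11351636434 -0.850650807746
0.500000001592 0.688190960484 -1.37638191977
-0.809016992934 -0.262865555603 -1.37638192141
1.34696407637e-09 -0.850650808024 -1.37638192067
-0.809016993636 -1.11351636408 -0.850650809488
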