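# 73|elongated pentagonal orthobirotunda (J42)|Johnson
1.61803398891 1.45759530859e-09 0.499999999486
1.3090169933 0.951056517351 0.500000000814
0.499999998157 1.53884176859 0.500000001832
-0.500000001843 1.53884176729 0.50000000215
-1.30901699545 0.951056513946 0.500000001647
-1.61803398859 -2.75130160098e-09 0.500000000514
-1.30901699298 -0.951056518645 0.499999999186
-0.49999999784 -1.53884176988 0.499999998168
0.50000000216 -1.53884176858 0.49999999785
1.30901699577 -0.951056515239 0.499999998353
-1.36078843813e-09 1.37638191872 1.35065081013
-0.500000000299 0.688190957158 1.87638192152
-1.3090169945 0.425325400726 1.35065080932
1.30901699425 0.425325404131 1.35065080849
0.809016995313 -0.262865557435 1.87638191987
0.809016996253 -1.11351636511 1.35065080665
0.499999999701 0.688190958458 1.8763819212
-0.809016993437 -0.262865559539 1.87638192039
1.70286252462e-09 -0.85065081078 1.87638191937
-0.809016992497 -1.11351636721 1.35065080717
1.61803398859 2.75130152844e-09 -0.500000000514
1.30901699298 0.951056518645 -0.499999999186
0.49999999784 1.53884176988 -0.499999998168
-0.50000000216 1.53884176858 -0.49999999785
-1.30901699577 0.951056515239 -0.499999998353
-1.61803398891 -1.45759538104e-09 -0.499999999486
-1.3090169933 -0.951056517351 -0.500000000814
-0.499999998157 -1.53884176859 -0.500000001832
0.500000001843 -1.53884176729 -0.50000000215
1.30901699545 -0.951056513946 -0.500000001647
-2.21951301779e-09 1.37638192222 -1.35065080657
-0.500000001492 0.688190962013 -1.87638191942
-1.30901699536 0.425325404221 -1.35065080739
1.30901699339 0.425325407626 -1.35065080822
0.80901699412 -0.26286555258 -1.87638192107
0.809016995394 -1.11351636161 -1.35065081005
0.499999998508 0.688190963313 -1.87638191974
-0.80901699463 -0.262865554684 -1.87638192055
5.0988555255e-10 -0.850650805925 -1.87638192157
-0.809016993356 -1.11351636372 -1.35065080954
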