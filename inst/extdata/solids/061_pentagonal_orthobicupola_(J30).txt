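# 61|pentagonal orthobicupola (J30)|Johnson
1.61803398875 -3.54950657644e-09 -1.66566576023e-09
1.30901699646 0.951056513424 -1.97282855874e-09
0.500000003376 1.53884176749 -1.52643793726e-09
-0.499999996624 1.53884176968 -4.96999906643e-10
-1.30901699229 0.951056519167 7.22275171564e-10
-1.61803398875 3.54950630986e-09 1.66566567558e-09
-1.30901699646 -0.951056513424 1.97282848804e-09
-0.500000003376 -1.53884176749 1.52643787995e-09
0.499999996624 -1.53884176968 4.96999857719e-10
1.30901699229 -0.951056519167 -7.22275234628e-10
0.809016995493 0.26286555463 0.525731111113
2.40729346733e-09 0.850650808698 0.52573111156
-0.809016993257 0.26286555818 0.525731112779
-0.500000000968 -0.688190958793 0.525731113086
0.499999999032 -0.688190960987 0.525731112057
0.80901699441 0.262865553939 -0.525731113125
1.32487826744e-09 0.850650808006 -0.525731112678
-0.80901699434 0.262865557489 -0.525731111459
-0.500000002051 -0.688190959484 -0.525731111152
0.499999997949 -0.688190961678 -0.525731112181
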