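# 69|elongated pentagonal orthobicupola (J38)|Johnson
1.61803398875 -6.91047051875e-09 0.5
1.30901699844 0.951056510704 0.5
0.500000006572 1.53884176645 0.5
-0.499999993428 1.53884177072 0.5
-1.30901699031 0.951056521886 0.5
-1.61803398875 6.91047046395e-09 0.5
-1.30901699844 -0.951056510704 0.5
-0.500000006572 -1.53884176645 0.5
0.499999993428 -1.53884177072 0.5
1.30901699031 -0.951056521886 0.5
0.809016995498 0.262865552604 1.02573111212
3.63304936452e-09 0.850650808352 1.02573111212
-0.809016993252 0.262865559515 1.02573111212
-0.500000002939 -0.6881909581 1.02573111212
0.499999997061 -0.688190962371 1.02573111212
1.61803398875 -6.9104703961e-09 -0.5
1.30901699844 0.951056510704 -0.5
0.500000006572 1.53884176645 -0.5
-0.499999993428 1.53884177072 -0.5
-1.30901699031 0.951056521886 -0.5
-1.61803398875 6.9104705866e-09 -0.5
-1.30901699844 -0.951056510704 -0.5
-0.500000006572 -1.53884176645 -0.5
0.499999993428 -1.53884177072 -0.5
1.30901699031 -0.951056521886 -0.5
0.809016995498 0.262865552604 -1.02573111212
3.63304898487e-09 0.850650808352 -1.02573111212
-0.809016993252 0.262865559515 -1.02573111212
-0.500000002939 -0.6881909581 -1.02573111212
0.499999997061 -0.688190962371 -1.02573111212
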