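# 74|elongated pentagonal gyrobirotunda (J43)|Johnson
1.61803398885 6.48943800342e-09 0.499999999682
1.3090169903 0.951056521428 0.500000000906
0.499999993345 1.53884177017 0.500000001785
-0.500000006655 1.53884176578 0.500000001981
-1.30901699845 0.951056509938 0.500000001421
-1.61803398865 -7.71302465484e-09 0.500000000318
-1.3090169901 -0.951056522652 0.499999999094
-0.499999993148 -1.53884177139 0.499999998215
0.500000006852 -1.53884176701 0.499999998019
1.30901699865 -0.951056511162 0.499999998579
-5.77509192418e-09 1.37638191882 1.35065081004
-0.500000002651 0.688190955745 1.87638192141
-1.30901699598 0.425325396778 1.35065080913
1.30901699277 0.425325408268 1.35065080862
0.809016995898 -0.262865554805 1.87638191999
0.809016999528 -1.11351636251 1.35065080683
0.499999997349 0.688190960134 1.87638192121
-0.809016992852 -0.262865561906 1.87638192031
4.10228782326e-09 -0.850650810648 1.87638191943
-0.809016989222 -1.11351636961 1.35065080715
1.61803398865 7.71302453854e-09 -0.500000000318
1.3090169901 0.951056522652 -0.499999999094
0.499999993148 1.53884177139 -0.499999998215
-0.500000006852 1.53884176701 -0.499999998019
-1.30901699865 0.951056511162 -0.499999998579
-1.61803398885 -6.48943812913e-09 -0.499999999682
-1.3090169903 -0.951056521428 -0.500000000906
-0.499999993345 -1.53884177017 -0.500000001785
0.500000006655 -1.53884176578 -0.500000001981
1.30901699845 -0.951056509938 -0.500000001421
-0.809016999528 1.11351636251 -1.35065080683
-0.809016995898 0.262865554805 -1.87638191999
-1.30901699277 -0.425325408268 -1.35065080862
0.809016989222 1.11351636961 -1.35065080715
0.809016992852 0.262865561906 -1.87638192031
1.30901699598 -0.425325396778 -1.35065080913
-4.10228794677e-09 0.850650810648 -1.87638191943
-0.499999997349 -0.688190960134 -1.87638192121
0.500000002651 -0.688190955745 -1.87638192141
5.77509212392e-09 -1.37638191882 -1.35065081004
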