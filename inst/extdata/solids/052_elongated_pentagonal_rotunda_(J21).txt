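# 52|elongated pentagonal rotunda (J21)|Johnson
1.61803398857 2.86423482529e-09 -0.0378387957959
1.30901699245 0.951056518591 -0.0378387970998
0.499999996992 1.5388417694 -0.0378387949803
-0.500000003008 1.53884176756 -0.037838790247
-1.3090169963 0.951056513779 -0.0378387847078
-1.61803398893 -3.08437932238e-09 -0.0378387804785
-1.30901699281 -0.951056518811 -0.0378387791746
-0.49999999735 -1.53884176962 -0.0378387812941
0.50000000265 -1.53884176778 -0.0378387860274
1.30901699594 -0.951056513999 -0.0378387915666
1.31720073522e-09 1.37638192284 0.812812016211
-0.499999994929 0.68819096321 1.3385431327
-1.30901699131 0.425325404134 0.812812025174
1.30901699744 0.425325408947 0.812812012782
0.809017001194 -0.262865550679 1.33854312927
0.809017000269 -1.11351636056 0.812812019625
0.500000005071 0.688190965048 1.33854312797
-0.809016987556 -0.262865553653 1.33854313693
7.89943560444e-09 -0.850650804458 1.33854313481
-0.809016988481 -1.11351636353 0.812812027283
1.61803398384 -4.47457461899e-11 -1.0378387958
1.30901698771 0.951056515682 -1.0378387971
0.499999992259 1.53884176649 -1.03783879498
-0.500000007741 1.53884176465 -1.03783879025
-1.30901700104 0.95105651087 -1.03783878471
-1.61803399366 -5.99335983568e-09 -1.03783878048
-1.30901699754 -0.95105652172 -1.03783877917
-0.500000002084 -1.53884177253 -1.03783878129
0.499999997916 -1.53884177069 -1.03783878603
1.30901699121 -0.951056516908 -1.03783879157
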