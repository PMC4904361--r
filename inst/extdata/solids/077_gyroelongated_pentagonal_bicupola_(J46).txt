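# 77|gyroelongated pentagonal bicupola (J46)|Johnson
1.61803398849 -2.94897956259e-08 0.431198502887
1.30901701267 0.951056492834 0.431198498127
0.500000029765 1.53884176091 0.43119849482
-0.499999970235 1.53884178042 0.431198494229
-1.30901697608 0.951056543907 0.431198496579
-1.618033989 3.36400036181e-08 0.431198500973
-1.30901701318 -0.951056488684 0.431198505733
-0.500000030275 -1.53884175676 0.43119850904
0.499999969725 -1.53884177627 0.431198509631
1.30901697557 -0.951056539757 0.431198507281
0.809016998937 0.262865544882 0.956929613262
1.60287698851e-08 0.850650812957 0.956929609955
-0.809016989813 0.262865576447 0.956929612305
-0.500000013991 -0.688190945876 0.956929617065
0.499999986009 -0.688190965385 0.956929617656
1.5388417786 0.499999967905 -0.431198503426
0.951056542087 1.30901697375 -0.431198507667
3.18198887537e-08 1.61803398667 -0.431198509716
-0.951056490504 1.30901701085 -0.431198508792
-1.53884175858 0.500000027945 -0.431198505246
-1.53884177809 -0.499999972055 -0.431198500434
-0.951056541577 -1.3090169779 -0.431198496193
-3.1309910494e-08 -1.61803399082 -0.431198494143
0.951056491014 -1.309017015 -0.431198495068
1.53884175909 -0.500000032095 -0.431198498614
0.688190970556 0.49999998197 -0.956929616048
-0.262865539711 0.809016994898 -0.956929618098
-0.850650807786 1.19895121452e-08 -0.956929614552
-0.262865571276 -0.809016993852 -0.956929610311
0.688190951047 -0.50000001803 -0.956929611236
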