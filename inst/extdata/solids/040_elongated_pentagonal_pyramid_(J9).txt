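# 40|elongated pentagonal pyramid (J9)|Johnson
0.850650808352 -3.02788097625e-17 0.40675171708
0.26286555606 0.809016994375 0.40675171708
-0.688190960236 0.5 0.40675171708
-0.688190960236 -0.5 0.40675171708
0.26286555606 -0.809016994375 0.40675171708
3.02788097625e-17 -3.02788097625e-17 0.932482829199
0.850650808352 -3.02788097625e-17 -0.59324828292
0.26286555606 0.809016994375 -0.59324828292
-0.688190960236 0.5 -0.59324828292
-0.688190960236 -0.5 -0.59324828292
0.26286555606 -0.809016994375 -0.59324828292
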