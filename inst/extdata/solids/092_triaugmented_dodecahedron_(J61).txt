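# 92|triaugmented dodecahedron (J61)|Johnson
-0.823329134681 -0.77154728332 -0.809017009326
-0.823329142188 -0.771547306664 0.809016979424
-0.823329161431 0.84648670543 -0.809016985982
-0.823329168938 0.846486682086 0.809017002768
0.794704854068 -0.77154725657 -0.80901700182
0.794704846562 -0.771547279914 0.80901698693
0.794704827318 0.84648673218 -0.809016978475
0.794704819812 0.846486708836 0.809017010274
-0.0143121430956 -0.462530268356 -1.30901700111
-1.32332914949 0.0374696983305 -0.500000005599
-0.514312135793 -1.27154728988 -2.07312602755e-08
-0.0143121552413 -0.462530306128 1.30901698764
1.29470483926 0.0374697416129 -0.499999993453
-0.514312179076 1.34648669887 1.7040422887e-08
-0.0143121596281 0.537469731644 -1.30901698669
-1.32332915413 0.037469683903 0.499999994401
0.485687864207 -1.27154727335 -1.60920291944e-08
-0.0143121717737 0.537469693872 1.30901700206
1.29470483462 0.0374697271854 0.500000006547
0.485687820924 1.3464867154 2.16796539441e-08
0.847491247909 0.0374697471238 -1.39442718653
-1.40873933419 -0.82433370917 -1.84285409842e-08
0.847491234971 0.0374697068876 1.39442719547
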