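# 38|elongated triangular pyramid (J7)|Johnson
0.57735026919 -4.75809867696e-17 0.311929059867
-0.288675134595 0.5 0.311929059867
-0.288675134595 -0.5 0.311929059867
5.55111512313e-17 -4.75809867696e-17 1.1284256408
0.57735026919 -4.75809867696e-17 -0.688070940133
-0.288675134595 0.5 -0.688070940133
-0.288675134595 -0.5 -0.688070940133
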