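# 35|square cupola (J4)|Johnson
1.30656296523 1.6480626252e-09 -0.235702258427
0.923879531708 0.92387953368 -0.235702258965
-1.28316326199e-09 1.30656296489 -0.235702260341
-0.923879533315 0.923879531363 -0.235702261749
-1.30656296452 -1.62839484081e-09 -0.235702262364
-0.923879530998 -0.92387953366 -0.235702261826
1.99329426831e-09 -1.30656296487 -0.23570226045
0.923879534025 -0.923879531343 -0.235702259042
0.653281481389 0.270598050873 0.471404521786
-0.270598051602 0.653281482079 0.471404520411
-0.653281482809 -0.270598050912 0.471404519796
0.270598050182 -0.653281482119 0.471404521171
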