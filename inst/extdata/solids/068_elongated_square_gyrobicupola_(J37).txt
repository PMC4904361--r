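# 68|elongated square gyrobicupola (J37)|Johnson
1.3065629653 7.37507937745e-10 0.499999998883
0.92387953322 0.923879533365 0.499999997113
8.24799093368e-10 1.30656296601 0.499999997034
-0.923879531803 0.923879533927 0.499999998693
-1.30656296445 1.53223632556e-09 0.500000001117
-0.923879532365 -0.923879531095 0.500000002887
3.00706065037e-11 -1.30656296374 0.500000002966
0.923879532658 -0.923879531657 0.500000001307
0.653281483552 0.270598052614 1.20710678001
-0.270598048842 0.65328148526 1.20710677994
-0.653281481489 -0.270598047135 1.20710678236
0.270598050906 -0.653281479781 1.20710678244
1.30656296445 -1.53223641364e-09 -0.500000001117
0.923879532365 0.923879531095 -0.500000002887
-3.00705761753e-11 1.30656296374 -0.500000002966
-0.923879532658 0.923879531657 -0.500000001307
-1.3065629653 -7.37507934673e-10 -0.499999998883
-0.92387953322 -0.923879533365 -0.499999997113
-8.24798987741e-10 -1.30656296601 -0.499999997034
0.923879531803 -0.923879533927 -0.499999998693
0.27059804924 0.653281479616 -1.2071067829
-0.653281483388 0.270598047532 -1.20710678124
-0.270598051304 -0.653281485096 -1.20710677947
0.653281481324 -0.270598053012 -1.20710678113
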