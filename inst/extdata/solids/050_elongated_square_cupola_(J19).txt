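# 50|elongated square cupola (J19)|Johnson
1.30656296463 1.34517093516e-09 0.258578645019
0.923879531297 0.923879533457 0.258578644722
-1.61378687329e-09 1.30656296486 0.258578643863
-0.923879533725 0.923879531526 0.258578642945
-1.30656296513 -1.38502807251e-09 0.258578642506
-0.923879531795 -0.923879533496 0.258578642803
1.11641211539e-09 -1.3065629649 0.258578643662
0.923879533228 -0.923879531566 0.25857864458
0.653281481227 0.270598050681 0.965685425598
-0.270598051684 0.653281482081 0.965685424739
-0.653281483084 -0.27059805083 0.9656854243
0.270598049827 -0.65328148223 0.965685425159
1.30656296559 1.42224084734e-09 -0.741421354981
0.923879532259 0.923879533534 -0.741421355278
-6.52039148905e-10 1.30656296493 -0.741421356137
-0.923879532763 0.923879531603 -0.741421357055
-1.30656296416 -1.30795812719e-09 -0.741421357494
-0.923879530833 -0.923879533419 -0.741421357197
2.07815988021e-09 -1.30656296482 -0.741421356338
0.92387953419 -0.923879531489 -0.74142135542
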