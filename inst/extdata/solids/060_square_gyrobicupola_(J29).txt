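# 60|square gyrobicupola (J29)|Johnson
1.30656296488 5.06303084259e-09 -8.55996581936e-09
0.923879528931 0.923879536091 -7.22221790165e-09
-5.06303065816e-09 1.30656296488 -1.65379272981e-09
-0.923879536091 0.923879528931 4.88340200253e-09
-1.30656296488 -5.06303076777e-09 8.55996590684e-09
-0.923879528931 -0.923879536091 7.22221784942e-09
5.06303070397e-09 -1.30656296488 1.65379253362e-09
0.923879536091 -0.923879528931 -4.8834018429e-09
0.653281486022 0.2705980535 0.707106776564
-0.270598047972 0.653281482285 0.707106782132
-0.653281476757 -0.27059805171 0.707106785809
0.270598057237 -0.653281480495 0.707106780241
0.270598042909 0.653281482592 -0.707106783786
-0.653281488119 0.270598046647 -0.707106777249
-0.270598052174 -0.653281484382 -0.707106778587
0.653281478854 -0.270598048437 -0.707106785124
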