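# 97|augmented truncated cube (J66)|Johnson
-0.933647701188 -1.2071067808 -0.50000000029
-0.933647700926 -0.499999999481 -1.20710678134
-0.226540919957 -1.20710678089 -1.20710678143
-0.933647701251 -1.20710678099 0.49999999971
-0.933647701078 -0.499999999944 1.20710678103
-0.226540920109 -1.20710678135 1.20710678094
-0.933647700617 0.500000000519 -1.20710678115
-0.933647700444 1.20710678157 -0.499999999827
-0.226540919213 1.20710678149 -1.20710678097
-0.933647700769 0.500000000056 1.20710678122
-0.933647700507 1.20710678138 0.500000000173
-0.226540919365 1.20710678102 1.2071067814
0.773459080043 -1.20710678119 -1.20710678137
1.48056586118 -1.20710678155 -0.500000000138
1.48056586145 -0.500000000225 -1.20710678119
0.773459079891 -1.20710678166 1.207106781
1.48056586112 -1.20710678174 0.499999999862
1.4805658613 -0.500000000688 1.20710678118
0.773459080787 1.20710678118 -1.20710678091
1.48056586176 0.499999999775 -1.207106781
1.48056586193 1.20710678083 -0.499999999675
0.773459080635 1.20710678072 1.20710678147
1.4805658616 0.499999999312 1.20710678138
1.48056586187 1.20710678063 0.500000000325
-1.64075448199 6.41541801962e-10 -0.70710678129
-1.64075448225 -0.707106780681 -2.39034410648e-10
-1.64075448208 3.70285078921e-10 0.707106781083
-1.64075448182 0.707106781692 3.22223097737e-11
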