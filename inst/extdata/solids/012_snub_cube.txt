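# 12|snub cube|Archimedean
-1.14261371233 -0.621226084559 0.337753885316
-1.14261352905 -0.337753709447 -0.621226517272
-1.1426134888 0.337754318029 0.621226260428
-1.14261330553 0.621226693141 -0.33775414216
-0.621226676886 -1.14261336519 -0.337753970203
-0.621226628926 -0.337753734942 1.14261346081
-0.621226192187 0.337754065821 -1.14261360045
-0.621226144227 1.14261369607 0.33775383056
-0.337754347926 -1.14261337905 0.621226446028
-0.337754010831 -0.621226394041 -1.14261350696
-0.337753936796 0.621226573937 1.14261343104
-0.337753599701 1.14261355895 -0.62122652195
0.337753739345 -1.1426136388 -0.621226299163
0.337753679952 -0.621226427072 1.14261358681
0.337754267676 0.621226247176 -1.14261351089
0.337754208283 1.1426134589 0.621226375085
0.621226068304 -1.14261365266 0.337754117068
0.621226449031 -0.337754212686 -1.1426134174
0.621226372082 0.337753881807 1.14261355704
0.621226752809 1.14261332178 -0.337753977424
1.14261338145 -0.621226736554 -0.337753805467
1.14261334916 -0.33775423818 0.621226560685
1.1426136687 0.337753629598 -0.621226303841
1.1426136364 0.621226127972 0.337754062312
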