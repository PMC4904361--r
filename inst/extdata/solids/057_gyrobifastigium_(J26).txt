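# 57|gyrobifastigium (J26)|Johnson
0.5 0.5 0
-0.5 0.5 0
-0.5 -0.5 0
0.5 -0.5 0
0.5 3.46944695195e-17 0.866025403784
-0.5 3.46944695195e-17 0.866025403784
6.27085542843e-17 0.5 -0.866025403784
1.47621432689e-18 -0.5 -0.866025403784
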