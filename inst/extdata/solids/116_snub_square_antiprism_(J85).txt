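# 116|snub square antiprism (J85)|Johnson
0.707106781187 4.79859494203e-17 0.676868509031
0.5 0.5 -0.676868509031
9.8808954043e-17 0.707106781187 0.676868509031
-0.5 0.5 -0.676868509031
-0.707106781187 1.34581555044e-16 0.676868509031
-0.5 -0.5 -0.676868509031
-7.43822572041e-17 -0.707106781187 0.676868509031
0.5 -0.5 -0.676868509031
0.857865868455 0.857865868455 0.185607021282
1.29798565654e-16 1.21320554587 -0.185607021282
-0.857865868455 0.857865868455 0.185607021282
-1.21320554587 1.96560778266e-16 -0.185607021282
-0.857865868455 -0.857865868455 0.185607021282
-1.67351092037e-16 -1.21320554587 -0.185607021282
0.857865868455 -0.857865868455 0.185607021282
1.21320554587 -2.4916370827e-16 -0.185607021282
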