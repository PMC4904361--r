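# 39|elongated square pyramid (J8)|Johnson
0.707106781187 -3.70074341542e-17 0.365877024313
6.84087557765e-17 0.707106781187 0.365877024313
-0.707106781187 4.95881714694e-17 0.365877024313
-1.04782455471e-16 -0.707106781187 0.365877024313
2.51109529647e-17 -3.70074341542e-17 1.0729838055
0.707106781187 -3.70074341542e-17 -0.634122975687
6.84087557765e-17 0.707106781187 -0.634122975687
-0.707106781187 4.95881714694e-17 -0.634122975687
-1.04782455471e-16 -0.707106781187 -0.634122975687
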