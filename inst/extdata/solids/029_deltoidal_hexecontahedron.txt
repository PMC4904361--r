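# 29|deltoidal hexecontahedron|Catalan
1.1283953954e-11 -0.766535558308 -2.00681614525
0.766535558251 -2.00681614527 9.18046147512e-12
-1.24028058695 -1.24028058689 -1.24028058696
-0.766535558373 -2.00681614522 -1.71068203582e-11
-5.7536614685e-11 -0.766535558316 2.00681614524
2.00681614523 -6.2059604395e-11 0.766535558346
1.24028058692 -1.24028058697 -1.24028058692
-2.00681614526 5.90311464107e-11 0.766535558278
2.00681614526 -5.90321665452e-11 -0.766535558278
5.75364718556e-11 0.766535558316 -2.00681614524
-1.24028058688 1.24028058697 -1.24028058695
-1.24028058699 -1.2402805869 1.24028058691
1.24028058688 -1.24028058697 1.24028058695
-2.00681614523 6.20595483182e-11 -0.766535558346
-0.766535558251 2.00681614527 -9.18043956183e-12
-1.12841230816e-11 0.766535558308 2.00681614525
1.24028058695 1.24028058689 1.24028058696
-1.24028058692 1.24028058697 1.24028058692
1.24028058699 1.2402805869 -1.24028058691
0.766535558373 2.00681614522 1.71069057542e-11
-3.73680226238e-11 -1.90921930201 -1.17996242063
-1.09388532213 -1.7699436309 -0.676058308868
2.18777064418 -6.60052987445e-11 3.75131414477e-11
0.676058308843 -1.09388532211 -1.76994363093
-1.90921930205 -1.17996242057 -3.50667528784e-11
-0.676058308848 -1.09388532207 -1.76994363095
-1.76994363094 -0.67605830879 -1.09388532212
-1.76994363097 -0.676058308795 1.09388532206
-6.60043128535e-11 -2.18777064418 -4.32051882118e-12
1.17996242059 -3.93697460219e-11 1.90921930204
1.7699436309 -0.676058308901 1.09388532212
1.90921930198 -1.17996242068 3.04066780475e-11
1.09388532205 -1.76994363097 -0.676058308831
-1.76994363093 0.676058308897 1.09388532206
1.76994363093 -0.676058308897 -1.09388532206
-1.17996242059 3.93694860906e-11 -1.90921930204
3.75130590766e-11 4.32048658664e-12 -2.18777064418
-0.676058308782 1.09388532211 -1.76994363094
-1.09388532202 1.76994363097 -0.676058308861
1.76994363094 0.67605830879 1.09388532212
-0.676058308909 -1.09388532207 1.76994363092
-1.09388532215 -1.7699436309 0.676058308824
-7.78335933852e-11 -1.90921930202 1.17996242062
0.676058308782 -1.09388532211 1.76994363094
1.09388532202 -1.76994363097 0.676058308861
-1.7699436309 0.676058308901 -1.09388532212
-1.90921930198 1.17996242068 -3.04063515787e-11
-2.18777064418 6.60051698153e-11 -3.75140485485e-11
-1.17996242066 3.18290026384e-11 1.909219302
-3.75131593548e-11 -4.32061551576e-12 2.18777064418
7.7833493107e-11 1.90921930202 -1.17996242062
0.676058308848 1.09388532207 1.76994363095
-0.676058308843 1.09388532211 1.76994363093
-1.09388532205 1.76994363097 0.676058308831
1.17996242066 -3.18293935718e-11 -1.909219302
0.676058308909 1.09388532207 -1.76994363092
3.73678568445e-11 1.90921930201 1.17996242063
6.60042125753e-11 2.18777064418 4.32058328575e-12
1.76994363097 0.676058308795 -1.09388532206
1.09388532213 1.7699436309 0.676058308868
1.90921930205 1.17996242057 3.50672103494e-11
1.09388532215 1.7699436309 -0.676058308824
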