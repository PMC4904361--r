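# 123|triangular hebesphenorotunda (J92)|Johnson
-0.809016991212 -1.04443645019 0.274636093312
-0.499999991489 -0.288675138405 0.851986362645
0.809016997538 -1.04443644947 0.274636077389
-1.42026070837e-10 -1.51152262781 -0.0821860063906
0.500000008511 -0.288675137964 0.851986352804
-1.30901699159 -0.178411046621 0.274636101881
-0.499999997837 1.22284749218 0.274636099824
-1.30901699552 0.755761313845 -0.0821859839555
8.12942289638e-09 0.5773502656 0.851986361374
0.500000002163 1.22284749262 0.274636089984
1.30901699716 -0.178411045466 0.274636076118
1.30901699323 0.755761315 -0.0821860097187
0.99999999351 3.22015047232e-09 -0.659536279052
0.499999993128 0.866025406784 -0.659536270482
-0.500000006872 0.866025406343 -0.659536260642
-1.00000000649 2.33794462359e-09 -0.659536259371
-0.500000006108 -0.866025401226 -0.65953626794
0.499999993892 -0.866025400785 -0.659536277781
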