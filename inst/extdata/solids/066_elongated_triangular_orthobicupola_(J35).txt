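# 66|elongated triangular orthobicupola (J35)|Johnson
1 -5.16111074057e-09 0.5
0.50000000447 0.866025401204 0.5
-0.49999999553 0.866025406365 0.5
-1 5.16110553227e-09 0.5
-0.50000000447 -0.866025401204 0.5
0.49999999553 -0.866025406365 0.5
0.50000000149 0.288675132014 1.31649658093
-0.49999999851 0.288675137175 1.31649658093
-2.97976852298e-09 -0.57735026919 1.31649658093
1 -5.16110549213e-09 -0.5
0.50000000447 0.866025401204 -0.5
-0.49999999553 0.866025406365 -0.5
-1 5.1611107807e-09 -0.5
-0.50000000447 -0.866025401204 -0.5
0.49999999553 -0.866025406365 -0.5
0.50000000149 0.288675132014 -1.31649658093
-0.49999999851 0.288675137175 -1.31649658093
-2.9797658392e-09 -0.57735026919 -1.31649658093
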