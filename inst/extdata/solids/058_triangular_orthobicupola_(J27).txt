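# 58|triangular orthobicupola (J27)|Johnson
1 -7.21963027125e-09 -2.22008606622e-09
0.500000006252 0.866025400175 -3.91862698506e-09
-0.499999993748 0.866025407394 -1.6985409062e-09
-1 7.21963015496e-09 2.22008613319e-09
-0.500000006252 -0.866025400175 3.91862696483e-09
0.499999993748 -0.866025407394 1.69854085784e-09
0.500000003897 0.288675133633 0.816496578881
-0.499999996103 0.288675140853 0.816496581102
-2.35556279104e-09 -0.577350266542 0.8164965828
0.500000000271 0.288675128337 -0.816496582974
-0.499999999729 0.288675135557 -0.816496580754
-5.98094822025e-09 -0.577350271838 -0.816496579055
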