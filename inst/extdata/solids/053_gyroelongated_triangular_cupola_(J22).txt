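# 53|gyroelongated triangular cupola (J22)|Johnson
0.999999999451 -5.77210113084e-09 0.178940557749
0.500000004258 0.866025400788 0.178940557288
-0.499999995742 0.866025406338 0.178940554221
-1.00000000055 5.32873256851e-09 0.178940551614
-0.500000005356 -0.866025401231 0.178940552075
0.499999994644 -0.866025406781 0.178940555142
0.499999998549 0.288675130586 0.9954371375
-0.500000001451 0.288675136137 0.995437134433
-6.25799802086e-09 -0.577350270423 0.995437134894
0.866025408635 0.499999996031 -0.67665911921
7.62604132049e-09 1.00000000084 -0.676659121247
-0.866025398934 0.500000005645 -0.676659124523
-0.866025404484 -0.499999994355 -0.676659125762
-3.47479224676e-09 -0.999999999162 -0.676659123725
0.866025403085 -0.500000003969 -0.676659120449
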