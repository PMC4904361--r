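# 67|elongated triangular gyrobicupola (J36)|Johnson
1.00000000175 -1.61922355893e-08 0.499999996498
0.500000012121 0.866025393579 0.500000005555
-0.499999987879 0.866025405554 0.500000009057
-0.999999998249 7.75627611802e-09 0.500000003502
-0.500000008619 -0.866025402015 0.499999994445
0.499999991381 -0.86602541399 0.499999990943
0.500000008067 0.288675117502 1.31649658161
-0.499999991933 0.288675129476 1.31649658511
-2.30300191631e-09 -0.577350280296 1.31649657606
0.999999998249 -7.75627620604e-09 -0.500000003502
0.500000008619 0.866025402015 -0.499999994445
-0.499999991381 0.86602541399 -0.499999990943
-1.00000000175 1.61922355911e-08 -0.499999996498
-0.500000012121 -0.866025393579 -0.500000005555
0.499999987879 -0.866025405554 -0.500000009057
2.3030019424e-09 0.577350280296 -1.31649657606
-0.500000008067 -0.288675117502 -1.31649658161
0.499999991933 -0.288675129476 -1.31649658511
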