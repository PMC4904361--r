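# 49|elongated triangular cupola (J18)|Johnson
0.999999999149 -9.62429755451e-11 0.236700687409
0.499999998701 0.866025403429 0.236700687857
-0.500000001299 0.866025402912 0.236700684263
-1.00000000085 -1.13120044625e-09 0.23670068022
-0.500000000403 -0.866025404657 0.236700679772
0.499999999597 -0.866025404139 0.236700683366
0.499999996065 0.288675132123 1.05319726729
-0.500000003935 0.288675131605 1.05319726369
-3.48668017733e-09 -0.57735027192 1.05319726325
1.00000000274 2.49657446611e-09 -0.763299312591
0.500000002295 0.866025406022 -0.763299312143
-0.499999997705 0.866025405505 -0.763299315737
-0.999999997257 1.46161694914e-09 -0.76329931978
-0.499999996808 -0.866025402064 -0.763299320228
0.500000003192 -0.866025401547 -0.763299316634
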