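# 41|gyroelongated square pyramid (J10)|Johnson
0.707106781187 -3.70074341542e-17 0.295164319981
9.26410483507e-17 0.707106781187 0.295164319981
-0.707106781187 4.95881714694e-17 0.295164319981
-8.05501628964e-17 -0.707106781187 0.295164319981
4.93432455389e-17 -3.70074341542e-17 1.00227110117
0.5 0.5 -0.545732095273
-0.5 0.5 -0.545732095273
-0.5 -0.5 -0.545732095273
0.5 -0.5 -0.545732095273
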