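# 32|square pyramid (J1)|Johnson
0.707106781187 -3.19744231092e-17 -0.141421356237
5.86888821304e-17 0.707106781187 -0.141421356237
-0.707106781187 5.46211825143e-17 -0.141421356237
-1.14502329117e-16 -0.707106781187 -0.141421356237
1.53910793186e-17 -3.19744231092e-17 0.565685424949
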