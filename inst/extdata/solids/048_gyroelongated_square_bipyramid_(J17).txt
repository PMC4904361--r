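# 48|gyroelongated square bipyramid (J17)|Johnson
0.707106781187 -3.00870439673e-17 0.420448207627
8.23776532786e-17 0.707106781187 0.420448207627
-0.707106781187 5.65085616562e-17 0.420448207627
-9.08135579685e-17 -0.707106781187 0.420448207627
3.90798504668e-17 -3.00870439673e-17 1.12755498881
0.5 0.5 -0.420448207627
-0.5 0.5 -0.420448207627
-0.5 -0.5 -0.420448207627
0.5 -0.5 -0.420448207627
3.90798504668e-17 -3.00870439673e-17 -1.12755498881
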