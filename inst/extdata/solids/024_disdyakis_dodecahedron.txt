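# 24|disdyakis dodecahedron|Catalan
-0.855414419841 -3.18864287552e-16 0.855414419841
-0.737306335125 -0.737306335125 0.737306335125
-0.855414419841 -0.855414419841 2.13504427813e-17
0.855414419841 3.29631972178e-16 0.855414419841
-1.39484041034 -3.76989655619e-16 2.13504427813e-17
-0.855414419841 0.855414419841 2.13504427813e-17
-0.737306335125 0.737306335125 -0.737306335125
-0.855414419841 -7.32919467142e-17 -0.855414419841
0.855414419841 0.855414419841 1.55658415745e-16
0.737306335125 0.737306335125 0.737306335125
1.39484041034 3.70732814098e-16 1.49639336803e-16
-0.737306335125 -0.737306335125 -0.737306335125
4.09770933695e-16 -0.855414419841 -0.855414419841
3.39607407742e-16 -1.39484041034 -2.88366345067e-16
0.855414419841 -0.855414419841 -1.12957530183e-16
0.737306335125 -0.737306335125 0.737306335125
2.98906198938e-17 -0.855414419841 0.855414419841
-0.737306335125 0.737306335125 0.737306335125
-2.79826167954e-16 -2.48700761598e-16 1.39484041034
-1.60049537007e-16 0.855414419841 0.855414419841
-2.79826167954e-16 1.39484041034 -1.0693845124e-16
0.737306335125 0.737306335125 -0.737306335125
-1.0441735307e-16 0.855414419841 -0.855414419841
4.67896301763e-16 6.101602625e-17 -1.39484041034
0.737306335125 -0.737306335125 -0.737306335125
0.855414419841 2.50956183151e-16 -0.855414419841
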