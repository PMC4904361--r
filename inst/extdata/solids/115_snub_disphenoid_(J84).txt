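# 115|snub disphenoid (J84)|Johnson
0.5 0 0.783930924233
-0.5 0 0.783930924233
0 0.5 -0.783930924233
0 -0.5 -0.783930924233
0.644584273224 3.51617405388e-17 -0.205561565853
-0.644584273224 -3.51617405388e-17 -0.205561565853
3.51617405388e-17 -0.644584273224 0.205561565853
-3.51617405388e-17 0.644584273224 0.205561565853
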