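# 21|triakis octahedron|Catalan
-0.404628215085 -0.404628215085 -0.404628215085
-0.404628215085 -0.404628215085 0.404628215085
-0.404628215085 0.404628215085 -0.404628215085
-0.404628215085 0.404628215085 0.404628215085
0.404628215085 -0.404628215085 0.404628215085
0.404628215085 0.404628215085 0.404628215085
0.404628215085 -0.404628215085 -0.404628215085
0.404628215085 0.404628215085 -0.404628215085
-0.976858924576 0 -0
0 0 0.976858924576
-0 -0.976858924576 0
0.976858924576 0 0
0 0.976858924576 0
0 -0 -0.976858924576
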