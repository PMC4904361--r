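# 19|triakis tetrahedron|Catalan
0.28927095594 0.28927095594 0.28927095594
-0.28927095594 -0.28927095594 0.28927095594
-0.28927095594 0.28927095594 -0.28927095594
0.28927095594 -0.28927095594 -0.28927095594
0.4821182599 0.4821182599 -0.4821182599
-0.4821182599 0.4821182599 0.4821182599
-0.4821182599 -0.4821182599 -0.4821182599
0.4821182599 -0.4821182599 0.4821182599
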