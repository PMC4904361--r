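# 85|augmented hexagonal prism (J54)|Johnson
0.895202120212 0.060505085298 0.500000000061
0.395202120784 0.926530489413 0.499999996694
-0.604797879216 0.926530490074 0.499999996375
-1.10479787979 0.0605050866198 0.499999999424
-0.604797880361 -0.805520317495 0.500000002791
0.395202119639 -0.805520318156 0.50000000311
0.89520212053 0.0605050815934 -0.499999999939
0.395202121103 0.926530485708 -0.500000003306
-0.604797878897 0.926530486369 -0.500000003625
-1.10479787947 0.0605050829152 -0.500000000576
-0.604797880042 -0.8055203212 -0.499999997209
0.395202119958 -0.805520321861 -0.49999999689
1.25757455555 -0.726061009279 3.09068175814e-09
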