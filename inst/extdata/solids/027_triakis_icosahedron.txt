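# 27|triakis icosahedron|Catalan
0.651801093612 -0.65180109363 0.651801093731
-4.99867278857e-11 -0.402835229701 1.05463632347
-0.651801093703 -0.651801093583 0.651801093687
-1.05463632346 6.97165256679e-11 0.402835229749
-0.651801093656 0.651801093733 0.651801093584
0.651801093703 0.651801093583 -0.651801093687
1.05463632346 -6.97164701567e-11 -0.402835229749
4.99863630879e-11 0.402835229701 -1.05463632347
-0.402835229823 -1.05463632343 6.9828860157e-11
-1.05463632343 6.00583847705e-12 -0.40283522982
-0.651801093659 -0.651801093686 -0.651801093628
2.10629052459e-11 -0.402835229868 -1.05463632341
0.651801093656 -0.651801093733 -0.651801093584
0.402835229823 1.05463632343 -6.98289119492e-11
-0.402835229747 1.05463632346 -9.69674229176e-11
-0.651801093612 0.65180109363 -0.651801093731
0.402835229747 -1.05463632346 9.69673349432e-11
-2.10627464096e-11 0.402835229868 1.05463632341
0.651801093659 0.651801093686 0.651801093628
1.05463632343 -6.0057829659e-12 0.40283522982
6.3719762668e-11 1.12344879575 -0.694329540519
-1.12344879583 -0.69432954039 1.70636824538e-11
0.694329540468 -1.13766135222e-10 -1.12344879579
-1.6943311259e-11 -1.12344879586 -0.694329540341
-0.694329540468 1.13766315461e-10 1.12344879579
-1.12344879578 0.694329540471 -9.27486069814e-11
-0.694329540392 -6.39133402392e-11 -1.12344879583
-6.37199427348e-11 -1.12344879575 0.694329540519
1.12344879578 -0.694329540471 9.27486175531e-11
1.69440666512e-11 1.12344879586 0.694329540341
0.694329540392 6.39138322979e-11 1.12344879583
1.12344879583 0.69432954039 -1.70635471542e-11
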