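# 30|disdyakis triacontahedron|Catalan
1.14895838442 -1.32895372064 0.586558641308
0.203640895564 -1.3689333836 1.23078274985
-0.819173007058 -1.69536521601 -0.111393579849
-0.480450638344 -0.38838793833 -1.74602302216
-0.46999111014 -1.41309264475 1.15758096672
-0.677532267124 -1.63367912088 0.549833572472
-1.52955582713 -0.0646884535384 1.042376504
-1.08922476113 -0.272781666376 1.51555130002
-0.819460493901 -0.886027022368 1.40488968072
-1.57071680571 -1.06286154348 0.668636370051
-1.29991113225 -1.2744149607 -0.341133341436
-1.4257681272 -0.428367601296 -1.10179891361
1.65541282209 -0.781358905863 -0.281710931821
0.857465697097 -1.19162432979 1.18427201087
1.00703015765 -0.581301622121 1.44161474956
-0.648382664446 0.200057283742 1.72332568138
1.82111410134 -0.149696704751 -0.467814586399
0.0569982403983 -0.573819618222 1.92649494835
-1.6542129386 -0.729508280757 -0.537692647182
-1.82649065155 -0.304725400247 -0.0367250688357
1.32869722565 -1.33702195496 -0.068206563217
0.319169990486 -1.9548927393 0.347023680281
0.648382664446 -0.200057283742 -1.72332568138
1.82649065155 0.304725400247 0.0367250688357
1.80320155788 -0.499968641247 0.7364754165
-0.144475397186 0.653437590969 1.76348017712
0.480450638344 0.38838793833 1.74602302216
-0.229644694889 1.20972650716 1.38350984543
-1.82111410134 0.149696704751 0.467814586399
-1.65541282209 0.781358905863 0.281710931821
-1.25469951325 0.943368152629 1.25685567976
-0.85202356001 1.56899066735 0.492542931525
-0.292477519627 1.64835094417 0.868971936334
0.27680974278 1.75732132193 0.515240272304
1.08922476113 0.272781666376 -1.51555130002
1.52955582713 0.0646884535384 -1.042376504
0.819460493901 0.886027022368 -1.40488968072
0.830496710717 1.29125509823 1.29878251623
1.05864547157 0.085561594667 1.55873831665
1.4257681272 0.428367601296 1.10179891361
-1.05864547157 -0.085561594667 -1.55873831665
-0.27680974278 -1.75732132193 -0.515240272304
0.819173007058 1.69536521601 0.111393579849
0.677532267124 1.63367912088 -0.549833572472
1.6542129386 0.729508280757 0.537692647182
1.57071680571 1.06286154348 -0.668636370051
1.29991113225 1.2744149607 0.341133341436
0.46999111014 1.41309264475 -1.15758096672
-0.0569982403983 0.573819618222 -1.92649494835
-0.203640895564 1.3689333836 -1.23078274985
-1.32869722565 1.33702195496 0.068206563217
-0.319169990486 1.9548927393 -0.347023680281
-1.00703015765 0.581301622121 -1.44161474956
-0.830496710717 -1.29125509823 -1.29878251623
0.144475397186 -0.653437590969 -1.76348017712
0.85202356001 -1.56899066735 -0.492542931525
-0.857465697097 1.19162432979 -1.18427201087
-1.80320155788 0.499968641247 -0.7364754165
-1.14895838442 1.32895372064 -0.586558641308
0.292477519627 -1.64835094417 -0.868971936334
1.25469951325 -0.943368152629 -1.25685567976
0.229644694889 -1.20972650716 -1.38350984543
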