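# 121|disphenocingulum (J90)|Johnson
0 0.5 1.10443794208
0 -0.5 1.10443794208
0.5 1.63497256273e-17 -1.10443794208
-0.5 1.63497256273e-17 -1.10443794208
0.767131113983 0.5 0.462947603915
0.767131113983 -0.5 0.462947603915
-0.767131113983 0.5 0.462947603915
-0.767131113983 -0.5 0.462947603915
0.5 0.767131113983 -0.462947603915
0.5 -0.767131113983 -0.462947603915
-0.5 0.767131113983 -0.462947603915
-0.5 -0.767131113983 -0.462947603915
-5.92803271751e-17 1.12648314708 0.32500297595
1.12648314708 7.56300528024e-17 -0.32500297595
5.92803271751e-17 -1.12648314708 0.32500297595
-1.12648314708 -4.29306015478e-17 -0.32500297595
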