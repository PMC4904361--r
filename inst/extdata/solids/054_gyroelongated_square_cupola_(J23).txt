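# 54|gyroelongated square cupola (J23)|Johnson
1.30656296387 -4.68400885923e-09 0.202696878171
0.92387953528 0.923879529389 0.202696873317
4.33094071402e-09 1.30656296553 0.202696867521
-0.923879529743 0.923879536932 0.202696864177
-1.30656296588 5.98324509113e-09 0.202696865245
-0.923879537285 -0.92387952809 0.202696870099
-6.33631302078e-09 -1.30656296423 0.202696875895
0.923879527737 -0.923879535633 0.202696879239
0.653281479042 0.270598050322 0.909803655259
-0.270598051907 0.653281486459 0.909803649462
-0.653281488043 -0.27059804449 0.90980365053
0.270598042906 -0.653281480627 0.909803656327
1.20710678648 0.499999992965 -0.657598693786
0.500000008181 1.20710677704 -0.65759869955
-0.499999991819 1.20710678112 -0.657598704497
-1.20710677589 0.50000000282 -0.657598705729
-1.20710677997 -0.49999999718 -0.657598702524
-0.500000001675 -1.20710678125 -0.65759869676
0.499999998325 -1.20710678534 -0.657598691813
1.2071067824 -0.500000007035 -0.657598690581
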