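# 75|gyroelongated triangular bicupola (J44)|Johnson
1.00000000182 3.39061941492e-09 0.427799834329
0.499999999678 0.866025405938 0.427799834601
-0.500000000322 0.866025403464 0.427799838856
-0.99999999818 -1.55756655924e-09 0.427799842839
-0.499999996037 -0.866025404105 0.427799842567
0.500000003963 -0.866025401631 0.427799838311
0.50000000458 0.288675138498 1.24429641677
-0.49999999542 0.288675136024 1.24429642102
6.72310092203e-09 -0.577350266524 1.24429642075
0.866025400727 0.500000001226 -0.42779984334
-4.29445053223e-09 0.999999999083 -0.427799840726
-0.866025406842 0.499999996941 -0.42779983597
-0.866025404368 -0.500000003059 -0.427799833827
6.53735427214e-10 -1.00000000092 -0.427799836441
0.866025403201 -0.499999998774 -0.427799841198
0.288675128063 0.499999998048 -1.24429642181
-0.577350274484 -4.09422227665e-09 -1.24429641705
0.288675130537 -0.500000001952 -1.24429641967
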