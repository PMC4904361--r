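# 103|gyrate rhombicosidodecahedron (J72)|Johnson
-2.11803398818 -0.499999995695 -0.500000006735
-2.11803399139 -0.499999995555 0.499999993265
-2.11803398611 0.500000004305 -0.500000006874
-2.11803398932 0.500000004445 0.499999993126
-1.80901699017 3.55413698547e-09 -1.30901700019
-1.80901699858 3.91898409457e-09 1.30901698856
-1.61803398885 -1.30901699115 -0.809016999391
-1.61803399405 -1.30901699092 0.809016989359
-1.61803398345 1.3090169976 -0.809016999755
-1.61803398865 1.30901699783 0.809016988994
-1.30901699811 -1.80901699167 -3.95324817992e-09
-1.30901699085 -0.809016991897 -1.61803399284
-1.30901700124 -0.809016991446 1.61803398466
-1.30901698751 0.809016996853 -1.61803399307
-1.3090169979 0.809016997304 1.61803398443
-1.30901699064 1.80901699708 -4.45745450574e-09
-0.809016993512 -1.61803398726 -1.30901699675
-0.809017001922 -1.6180339869 1.309016992
-0.809016986828 1.61803399024 -1.3090169972
-0.809016995238 1.6180339906 1.30901699155
-0.500000002769 -2.11803398779 -0.500000001311
-0.500000005981 -2.11803398765 0.499999998689
-0.499999994228 -0.499999999262 -2.11803399029
-0.500000007837 -0.499999998672 2.11803398721
-0.499999992163 0.500000000738 -2.11803399043
-0.500000005772 0.500000001328 2.11803398707
-0.499999994019 2.11803398971 -0.500000001901
-0.499999997231 2.11803398985 0.499999998099
3.10785184152e-09 -1.30901699463 -1.80901699419
-8.5154531729e-09 -1.30901699412 1.80901699456
8.51545322127e-09 1.30901699412 -1.80901699456
-3.10785172551e-09 1.30901699463 1.80901699419
0.499999997231 -2.11803398985 -0.499999998099
0.499999994019 -2.11803398971 0.500000001901
0.361803405954 -1.05438242891e-09 -2.20344418421
0.499999992163 -0.500000000738 2.11803399043
0.861803406632 0.809016992331 -1.89442718834
0.499999994228 0.499999999262 2.11803399029
0.500000005981 2.11803398765 -0.499999998689
0.500000002769 2.11803398779 0.500000001311
0.809016995238 -1.6180339906 -1.30901699155
0.809016986828 -1.61803399024 1.3090169972
0.809017001922 1.6180339869 -1.309016992
0.809016993512 1.61803398726 1.30901699675
1.30901699064 -1.80901699708 4.45745442369e-09
0.86180340329 -0.809016996419 -1.89442718812
1.30901698751 -0.809016996853 1.61803399307
1.67082039876 0.499999996355 -1.3944271857
1.30901699085 0.809016991897 1.61803399284
1.30901699811 1.80901699167 3.95324809472e-09
1.61803398865 -1.30901699783 -0.809016988994
1.61803398345 -1.3090169976 0.809016999755
1.61803399405 1.30901699092 -0.809016989359
1.61803398885 1.30901699115 0.809016999391
1.6708203967 -0.500000003645 -1.39442718556
1.80901699017 -3.5541371095e-09 1.30901700019
2.11803398932 -0.500000004445 -0.499999993126
2.11803398611 -0.500000004305 0.500000006874
2.11803399139 0.499999995555 -0.499999993265
2.11803398818 0.499999995695 0.500000006735
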