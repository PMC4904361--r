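# 76|gyroelongated square bicupola (J45)|Johnson
1.30656296929 1.56063469933e-08 0.430147771532
0.923879530033 0.923879545264 0.430147762863
-5.33135619765e-09 1.30656297074 0.43014776712
-0.923879534989 0.923879531486 0.430147781812
-1.30656296047 -3.87883644572e-09 0.430147798331
-0.923879521211 -0.923879533537 0.430147807
1.41538276901e-08 -1.30656295901 0.430147802742
0.923879543812 -0.923879519758 0.430147788051
0.653281492083 0.270598070447 1.13725455573
-0.270598043282 0.653281495923 1.13725455999
-0.653281468758 -0.270598039441 1.13725457651
0.270598066607 -0.653281464917 1.13725457225
1.20710677305 0.500000003137 -0.430147804127
0.499999986588 1.20710677905 -0.430147806514
-0.500000013412 1.20710677159 -0.430147796259
-1.20710678933 0.499999985135 -0.430147779368
-1.20710678187 -0.500000014865 -0.430147765736
-0.49999999541 -1.20710679078 -0.430147763349
0.50000000459 -1.20710678332 -0.430147773604
1.2071067805 -0.499999996863 -0.430147790495
0.499999984609 0.499999988225 -1.13725457806
-0.500000015391 0.499999980769 -1.13725456781
-0.500000007934 -0.500000019231 -1.13725455417
0.499999992066 -0.500000011775 -1.13725456443
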