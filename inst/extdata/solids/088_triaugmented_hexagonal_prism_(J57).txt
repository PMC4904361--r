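# 88|triaugmented hexagonal prism (J57)|Johnson
0.999999998993 1.27762339919e-08 0.500000002014
0.499999987879 0.866025410144 0.500000001107
-0.500000012121 0.86602539731 0.499999999092
-1.00000000101 -1.28909572653e-08 0.499999997986
-0.499999989893 -0.866025410259 0.499999998893
0.500000010107 -0.866025397425 0.500000000908
1.00000000101 1.28909572998e-08 -0.499999997986
0.499999989893 0.866025410259 -0.499999998893
-0.500000010107 0.866025397425 -0.500000000908
-0.999999998993 -1.27762338892e-08 -0.500000002014
-0.499999987879 -0.866025410144 -0.500000001107
0.500000012121 -0.86602539731 -0.499999999092
1.36237244579 -0.786566075001 2.65409789684e-09
-1.3623724256 -0.78656610997 -2.83457290395e-09
-2.01889422264e-08 1.57313218497 1.80474824727e-10
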