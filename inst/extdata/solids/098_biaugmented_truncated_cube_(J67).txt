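# 98|biaugmented truncated cube (J67)|Johnson
-1.20710678067 -1.20710678177 -0.499999999831
-1.20710678105 -0.500000000626 -1.20710678106
-0.499999999543 -1.20710678149 -1.20710678107
-1.20710678059 -1.20710678171 0.500000000169
-1.20710678086 -0.500000000483 1.20710678131
-0.499999999348 -1.20710678135 1.2071067813
-1.20710678151 0.499999999374 -1.20710678112
-1.20710678178 1.2071067806 -0.499999999973
-0.500000000652 1.20710678089 -1.20710678122
-1.20710678132 0.499999999517 1.20710678125
-1.2071067817 1.20710678066 0.500000000027
-0.500000000457 1.20710678103 1.20710678116
0.500000000457 -1.20710678103 -1.20710678116
1.2071067817 -1.20710678066 -0.500000000027
1.20710678132 -0.499999999517 -1.20710678125
0.500000000652 -1.20710678089 1.20710678122
1.20710678178 -1.2071067806 0.499999999973
1.20710678151 -0.499999999374 1.20710678112
0.499999999348 1.20710678135 -1.2071067813
1.20710678086 0.500000000483 -1.20710678131
1.20710678059 1.20710678171 -0.500000000169
0.499999999543 1.20710678149 1.20710678107
1.20710678105 0.500000000626 1.20710678106
1.20710678067 1.20710678177 0.499999999831
-1.91421356243 -9.20859705689e-10 -0.707106781032
-1.91421356205 -0.707106782066 1.96641757259e-10
-1.91421356232 -8.37506202249e-10 0.707106781342
-1.9142135627 0.707106780307 1.13288487577e-10
1.91421356243 9.20859440483e-10 0.707106781032
1.9142135627 -0.707106780307 -1.13288375459e-10
1.91421356232 8.37506174131e-10 -0.707106781342
1.91421356205 0.707106782066 -1.96641876302e-10
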