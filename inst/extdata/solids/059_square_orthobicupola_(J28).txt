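# 59|square orthobicupola (J28)|Johnson
1.30656296488 -5.10155181009e-09 -1.02044400841e-08
0.923879536119 0.923879528904 -1.13103839821e-08
5.10155193198e-09 1.30656296488 -5.79085831726e-09
-0.923879528904 0.923879536119 3.12087379179e-09
-1.30656296488 5.10155184162e-09 1.02044401723e-08
-0.923879536119 -0.923879528904 1.1310383924e-08
-5.10155184162e-09 -1.30656296488 5.79085821707e-09
0.923879528904 -0.923879536119 -3.12087368495e-09
0.653281489017 0.270598050656 0.707106774885
-0.270598042 0.653281486629 0.707106780405
-0.653281477972 -0.270598044388 0.707106787488
0.270598053045 -0.653281480361 0.707106781969
0.653281477972 0.270598044388 -0.707106787488
-0.270598053045 0.653281480361 -0.707106781969
-0.653281489017 -0.270598050656 -0.707106774885
0.270598042 -0.653281486629 -0.707106780405
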