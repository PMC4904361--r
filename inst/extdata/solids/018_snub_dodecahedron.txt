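# 18|snub dodecahedron|Archimedean
1.41526541662 0.728335172825 -1.45402423106
1.74618644129 -0.192893714905 -1.24950378748
1.10315683548 -0.847550051467 -1.64691793801
0.374821658632 -0.330921030683 -2.09705383422
0.567715369958 0.643029600298 -1.9778389671
-0.374821657595 0.330921018779 -2.09705383628
-0.56771536898 -0.643029611526 -1.97783896374
-1.4152654159 -0.72833518108 -1.45402422762
-1.74618644068 0.192893707812 -1.24950378944
-1.10315683466 0.847550042118 -1.64691794337
-2.09705383534 -0.374821657168 0.330921025275
-1.97783896526 -0.567715371285 -0.643029604792
-1.45402422916 -1.41526541832 -0.7283351733
-1.24950378852 -1.74618644043 0.192893716
-1.6469179409 -1.10315683266 0.847550049513
-1.45402422951 1.41526541833 0.72833517258
-1.24950378841 1.74618644044 -0.192893716618
-1.64691794048 1.10315683267 -0.847550050328
-2.09705383517 0.374821657182 -0.330921026313
-1.97783896558 0.567715371299 0.643029603813
0.728335176602 -1.45402422532 1.41526542056
-0.192893711789 -1.24950378351 1.74618644448
-0.847550047068 -1.64691793756 1.10315683954
-0.33092102483 -2.09705383419 0.374821663985
0.643029605767 -1.97783896381 0.56771537524
0.330921024816 -2.09705383632 -0.37482165208
-0.64302960578 -1.97783896703 -0.567715364012
-0.728335176612 -1.45402423335 -1.41526541231
0.19289371178 -1.24950379342 -1.74618643739
0.847550047056 -1.64691794382 -1.10315683019
1.45402422915 -1.41526541419 0.728335181334
1.2495037885 -1.74618644154 -0.192893706087
1.6469179409 -1.10315683748 -0.84755004325
2.09705383533 -0.374821659061 -0.330921023147
1.97783896526 -0.567715367648 0.643029608015
-1.41526541661 0.728335181089 1.45402422692
-1.7461864413 -0.1928937078 1.24950378858
-1.10315683548 -0.847550042111 1.64691794282
-0.374821658635 -0.330921018776 2.0970538361
-0.567715369954 0.64302961153 1.97783896345
0.374821657597 0.330921030681 2.09705383441
0.567715368975 -0.643029600302 1.97783896739
1.41526541589 -0.728335172835 1.45402423176
1.74618644068 0.192893714893 1.24950378835
1.10315683467 0.84755005146 1.64691793856
0.728335177312 1.45402422532 -1.4152654202
-0.192893710916 1.24950378351 -1.74618644458
-0.847550046511 1.64691793756 -1.10315683996
-0.33092102463 2.09705383419 -0.374821664149
0.643029606061 1.97783896381 -0.567715374922
2.09705383517 0.374821659047 0.330921024185
1.97783896558 0.567715367635 -0.643029607036
1.45402422952 1.41526541418 -0.728335180614
1.24950378842 1.74618644153 0.192893706705
1.64691794048 1.10315683747 0.847550044065
0.330921024644 2.09705383631 0.374821652244
-0.643029606048 1.97783896703 0.567715363694
-0.728335177302 1.45402423336 1.41526541195
0.192893710925 1.24950379342 1.74618643749
0.847550046522 1.64691794382 1.10315683061
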