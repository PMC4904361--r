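# 101|metabiaugmented truncated dodecahedron (J70)|Johnson
-1.42226058125 -1.43480201864 -2.04804560281
-2.23127757528 -1.12578502431 -1.54804560223
-1.73127757499 -1.93480201863 -1.23902860818
-1.73127757306 -1.93480201851 1.37900538057
-1.42226057813 -1.43480201845 2.18802237469
-2.2312775729 -1.12578502416 1.68802237527
-2.23127757547 1.49224896444 -1.54804560234
-1.73127757531 2.30126595887 -1.23902860837
-1.42226058149 1.80126595886 -2.04804560295
-1.73127757338 2.30126595899 1.37900538038
-2.23127757309 1.49224896459 1.68802237516
-1.42226057837 1.80126595905 2.18802237455
1.1957734075 -1.43480201845 -2.04804560474
2.00479040222 -1.12578502399 -1.54804560535
1.50479040251 -1.93480201839 -1.23902861057
1.19577341062 -1.43480201826 2.18802237276
1.50479040444 -1.93480201827 1.37900537818
2.0047904046 -1.12578502385 1.68802237215
2.00479040203 1.49224896476 -1.54804560546
1.19577340726 1.80126595905 -2.04804560488
1.50479040219 2.30126595911 -1.23902861076
1.19577341038 1.80126595924 2.18802237262
2.00479040441 1.4922489649 1.68802237204
1.50479040412 2.30126595923 1.37900537799
-0.613243587267 -1.12578502423 -2.54804560342
0.386756412733 -1.12578502416 -2.54804560415
-0.113243587555 -0.316768029833 -2.8570625982
-2.73127757511 -0.316768029955 -1.23902860752
-2.73127757519 0.683231970045 -1.23902860756
-3.04029456893 0.183231970059 -0.430011612938
-1.42226057998 -2.43480201857 -0.430011614012
-1.42226057925 -2.43480201853 0.569988385988
-0.613243585218 -2.74381901286 0.0699883854056
-0.613243583409 -1.125785024 2.68802237408
0.386756416591 -1.12578502392 2.68802237335
-0.113243583242 -0.31676802957 2.99703936805
2.50479040239 -0.316768029567 -1.23902861138
2.50479040231 0.683231970433 -1.23902861142
2.81380739732 0.183231970493 -0.430011617251
-1.42226058037 2.80126595893 -0.430011614248
-1.42226057964 2.80126595897 0.569988385752
-0.613243585652 3.11028295339 0.0699883851422
-0.613243587461 1.49224896452 -2.54804560353
0.386756412539 1.49224896459 -2.54804560427
-0.113243587629 0.683231970167 -2.85706259824
-2.73127757318 -0.316768029837 1.37900538123
-2.73127757326 0.683231970163 1.37900538119
-3.04029456819 0.183231970104 0.569988387062
1.19577340877 -2.43480201838 -0.430011615941
1.1957734095 -2.43480201833 0.569988384059
0.386756414782 -2.74381901279 0.0699883846688
-0.613243583603 1.49224896475 2.68802237396
0.386756416397 1.49224896483 2.68802237323
-0.113243583316 0.68323197043 2.99703936801
2.50479040432 -0.316768029449 1.37900537737
2.50479040424 0.683231970551 1.37900537733
2.81380739806 0.183231970538 0.569988382749
1.19577340838 2.80126595912 -0.430011616177
1.19577340911 2.80126595917 0.569988383823
0.386756414348 3.11028295346 0.0699883844055
0.386756416327 -2.02021221494 2.24080877789
-0.613243583673 -2.02021221502 2.24080877862
-0.922260578607 -2.52021221508 1.4317917845
-0.113243584577 -2.82922920941 0.931791783916
0.695773410143 -2.52021221496 1.43179178331
2.05757680615 0.68323197036 -2.13345580209
2.05757680623 -0.31676802964 -2.13345580205
1.24855981151 -0.625785024097 -2.63345580144
0.74855981122 0.183231970227 -2.94247279548
1.24855981139 0.992248964653 -2.63345580151
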