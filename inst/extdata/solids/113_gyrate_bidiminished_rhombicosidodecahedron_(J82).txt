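# 113|gyrate bidiminished rhombicosidodecahedron (J82)|Johnson
-2.29365704559 0.567082045408 -0.391458984129
-2.29365704738 0.567082044854 0.608541015871
-1.98464005104 0.0670820450662 -1.20047597823
-1.98464005573 0.0670820436153 1.41755801052
-1.79365704296 1.37609903868 -0.700475977161
-1.79365704586 1.37609903778 0.917558011589
-1.48464005256 -0.741934950416 -1.50949297216
-1.48464005835 -0.74193495221 1.72657500534
-1.48464004842 0.876099038334 -1.50949297126
-1.48464005421 0.87609903654 1.72657500624
-1.48464004876 1.87609903744 0.108541018044
-0.98464005518 -1.55095194624 -1.20047597733
-0.984640059867 -1.55095194769 1.41755801142
-0.984640046903 1.68511603126 -1.20047597554
-0.675623063532 -2.05095194748 -0.391458982684
-0.675623065322 -2.05095194803 0.608541017316
-0.675623056497 -0.432917957833 -2.00949297054
-0.675623064081 -0.432917960181 2.22657500696
-0.67562305394 0.567082042167 -2.00949296998
-0.675623061523 0.567082039819 2.22657500752
-0.675623052698 2.18511603002 -0.391458980336
-0.17562305912 -1.24193495366 -1.70047597572
-0.175623065597 -1.24193495566 1.91755801303
-0.175623052424 1.37609903509 -1.70047597426
0.324376936468 -2.05095195004 -0.391458980893
0.324376934678 -2.05095195059 0.608541019107
0.186180343809 0.0670820400098 -2.09490316534
0.324376935919 -0.432917962739 2.22657500875
0.686180345325 0.876099032935 -1.78588616962
0.324376938477 0.567082037261 2.22657500931
0.324376947302 2.18511602746 -0.391458978546
0.63339393357 -1.55095195038 -1.20047597444
0.633393928883 -1.55095195183 1.41755801431
0.633393941846 1.68511602712 -1.20047597264
1.13339393074 -1.74193495801 0.108541020726
0.686180341187 -0.741934955815 -1.78588617052
1.1333939304 -0.741934958906 1.72657501003
1.49519733801 0.567082036214 -1.28588616835
1.13339393454 0.876099029844 1.72657501093
1.13339393999 1.87609903074 0.108541022731
1.44241092784 -1.24193495835 -0.700475972819
1.44241092494 -1.24193495925 0.917558015931
1.44241093454 1.3760990304 -0.700475971368
1.44241093164 1.3760990295 0.917558017382
1.49519733546 -0.432917963786 -1.2858861689
1.63339393302 0.0670820343618 1.417558017
1.94241092936 -0.432917965426 -0.3914589771
1.94241092757 -0.43291796598 0.6085410229
1.94241093191 0.567082034574 -0.391458976546
1.94241093012 0.56708203402 0.608541023454
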