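# 112|metabidiminished rhombicosidodecahedron (J81)|Johnson
-2.18511603065 0.391458976424 -0.675623052917
-2.18511602735 0.391458979382 0.324376947083
-1.87609903852 -0.108541025697 -1.48464004684
-1.87609902986 -0.108541017955 1.13339394191
-1.68511603238 1.20047597032 -0.984640051339
-1.68511602703 1.20047597511 0.633393937411
-1.37609903883 -0.917558020548 -1.79365704047
-1.37609902812 -0.917558010978 1.44241093703
-1.37609904025 0.700475968202 -1.79365704526
-1.37609902954 0.700475977772 1.44241093224
-1.37609903577 1.70047597299 -0.175623059465
-0.876099037098 -1.72657501357 -1.48464004536
-0.876099028438 -1.72657500583 1.13339394339
-0.876099039934 1.50949296393 -1.48464005493
-0.876099031274 1.50949297167 1.13339393382
-0.567082039608 -2.22657501091 -0.675623050527
-0.567082036301 -2.22657500795 0.324376949473
-0.567082046378 -0.608541026943 -2.29365704406
-0.567082032367 -0.608541014415 1.94241093344
-0.567082047255 0.391458973057 -2.29365704702
-0.567082033243 0.391458985585 1.94241093048
-0.567082043321 2.00949296659 -0.675623063055
-0.567082040013 2.00949296955 0.324376936945
-0.0670820446473 -1.41755801997 -1.98464004895
-0.0670820326798 -1.41755800927 1.6333939398
-0.0670820469418 1.20047596878 -1.98464005669
-0.0670820349743 1.20047597948 1.63339393206
0.432917960392 -2.22657501003 -0.675623053835
0.432917963699 -2.22657500707 0.324376946165
0.432917967633 -0.608541013539 1.94241093013
0.432917966757 0.391458986461 1.94241092717
0.432917956679 2.00949296747 -0.675623066362
0.432917959987 2.00949297043 0.324376933638
0.741934951652 -1.72657501215 -1.48464005071
0.741934960312 -1.72657500441 1.13339393804
0.741934948816 1.50949296535 -1.48464006028
0.741934957476 1.50949297309 1.13339392847
1.24193495615 -1.91755801347 -0.175623057424
1.24193496063 -0.917558008683 1.44241092837
1.24193495921 0.700475980067 1.44241092358
1.24193495298 1.70047597528 -0.175623068124
1.55095194741 -1.41755801559 -0.9846400543
1.55095195276 -1.4175580108 0.63339393445
1.55095194512 1.20047597316 -0.984640062043
1.55095195047 1.20047597794 0.633393926707
1.74193495889 -0.108541014784 1.13339392995
2.05095194772 -0.608541019863 -0.675623063972
2.05095195103 -0.608541016906 0.324376936028
2.05095194685 0.391458980137 -0.675623066929
2.05095195015 0.391458983094 0.324376933071
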