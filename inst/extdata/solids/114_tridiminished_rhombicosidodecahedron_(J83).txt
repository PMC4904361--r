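# 114|tridiminished rhombicosidodecahedron (J83)|Johnson
-2.19256958849 0.574535597243 -0.574535599392
-2.19256958809 0.574535598996 0.425464400608
-1.88355259421 0.0745355959654 -1.38355259301
-1.88355259317 0.0745356005558 1.23448139574
-1.69256958898 1.3835525913 -0.883552595383
-1.69256958834 1.38355259414 0.734481393367
-1.38355259396 -0.734481398723 -1.69256958617
-1.38355259268 -0.734481393049 1.54349839133
-1.3835525947 0.883552590026 -1.692569589
-1.38355259342 0.883552595701 1.5434983885
-1.38355259451 1.88355259286 -0.0745356020063
-0.883552593467 -1.54349839233 -1.38355259057
-0.883552592434 -1.54349838774 1.23448139818
-0.883552594943 1.69256958517 -1.38355259624
-0.574535598545 -2.04349839077 -0.57453559544
-0.57453559815 -2.04349838902 0.42546440456
-0.574535599922 -0.425464404856 -2.19256958703
-0.574535598249 -0.425464397429 2.04349839047
-0.574535600378 0.574535595144 -2.19256958878
-0.574535598705 0.574535602571 2.04349838872
-0.574535600476 2.19256958673 -0.574535602868
-0.0745355994308 -1.23448139846 -1.88355259143
-0.0745355980024 -1.23448139212 1.73448139732
-0.0745356006244 1.38355259029 -1.88355259602
0.425464401455 -2.04349839031 -0.574535595835
0.42546440185 -2.04349838856 0.425464404165
0.425464401751 -0.425464396973 2.04349839008
0.425464401295 0.574535603027 2.04349838832
0.425464399524 2.19256958719 -0.574535603262
0.734481395282 -1.54349839159 -1.38355259121
0.734481396316 -1.543498387 1.23448139754
0.734481393807 1.69256958591 -1.38355259688
1.23448139589 -1.73448139469 -0.0745355966962
1.23448139607 -0.734481391856 1.5434983903
1.23448139533 0.883552596894 1.54349838746
1.23448139424 1.88355259406 -0.0745356030399
1.54349838971 -1.23448139597 -0.88355259207
1.54349839035 -1.23448139313 0.73448139668
1.54349838852 1.38355259278 -0.88355259666
1.54349838916 1.38355259562 0.73448139209
1.73448139558 0.0745356022052 1.23448139431
2.04349838947 -0.425464400826 -0.574535599311
2.04349838986 -0.425464399072 0.425464400689
2.04349838901 0.574535599174 -0.574535601064
2.04349838941 0.574535600928 0.425464398936
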