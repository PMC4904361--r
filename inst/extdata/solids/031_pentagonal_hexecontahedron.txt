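# 31|pentagonal hexecontahedron|Catalan
1.67881416247 2.01614421043 0.96120035902
1.0887150932 2.4618121956 0.749226774069
-2.3044816399 -0.494660602471 -1.50061182832
2.01614420812 -0.961200369099 -1.67881415948
2.46181219375 -0.749226783886 -1.08871509064
-2.46181219375 -0.749226777689 1.08871509489
-1.61319151616 -1.61319151118 1.61319151994
-2.01614420813 -0.961200359556 1.67881416493
-1.67881416246 2.01614420499 -0.961200370465
-2.30448164064 0.494660602486 1.50061182718
-2.61019870311 2.83866081059e-09 0.997007186457
-2.17347476123 1.2157665505 1.26691742293
2.30448164064 0.494660593952 -1.50061182999
2.61019870311 -2.8386618509e-09 -0.997007186457
-1.21576654743 1.2669174331 2.17347475703
-1.61319151615 1.61319152034 1.61319151078
2.0161442073 0.961200369086 1.67881416047
1.61319151537 1.61319152033 1.61319151158
1.26691742661 -2.17347475748 1.21576655338
0.997007187112 2.61019870286 -7.16206227552e-09
-1.61319151536 1.61319151119 -1.61319152074
-2.01614420729 0.961200359569 -1.67881416593
-0.961200363823 1.67881415699 -2.01614421271
-0.749226780175 1.08871508639 -2.46181219676
-0.254566181885 -0.288337440413 -2.76752925532
6.49179344587e-10 0.997007179694 -2.61019870569
0.254566183254 0.288337424702 -2.76752925683
-1.67881416295 -2.01614420498 0.961200369635
-2.46181219321 0.749226777706 -1.08871509611
-2.61019870262 -2.82111557984e-09 -0.997007187749
-2.76752925601 -0.254566183378 -0.288337432521
-2.76752925615 0.254566183396 0.288337431151
-1.50061182927 2.30448164168 0.494660591307
-1.26691742722 2.17347476438 1.21576654041
-0.494660598784 1.5006118357 2.30448163589
0.961200363834 1.67881416842 2.01614420318
1.21576654635 -1.26691742076 2.17347476482
1.61319151536 -1.61319151119 1.61319152074
2.3044816399 -0.494660593967 1.50061183113
2.17347476061 -1.21576654331 1.26691743091
2.46181219322 0.749226783869 1.08871509185
2.76752925615 0.254566181741 -0.288337432596
2.767529256 -0.254566181759 0.288337433966
2.61019870262 2.82111664396e-09 0.997007187749
1.50061182902 -2.30448163887 0.494660605131
0.997007187094 -2.61019870287 7.65543185074e-09
2.17347476124 1.21576654329 -1.26691742984
1.50061182928 2.30448163886 -0.494660604389
0.749226781393 -1.08871510036 -2.46181219021
6.42476563015e-10 -0.997007194511 -2.61019870003
0.494660597644 -1.50061182262 2.30448164465
-0.961200364832 -1.67881415698 2.01614421224
-6.49179028779e-10 -0.997007179694 2.61019870569
-0.7492267814 -1.08871508638 2.46181219639
0.288337432631 2.76752925535 -0.254566190353
-1.08871509318 2.46181219136 -0.749226788044
-0.997007187094 2.61019870287 -7.65543238322e-09
-0.288337432612 2.7675292568 0.254566174642
-0.254566183252 0.288337440415 2.7675292552
0.254566181883 -0.288337424704 2.76752925696
0.749226780182 1.08871510036 2.46181219058
-6.42475709906e-10 0.997007194511 2.61019870003
1.21576654744 1.26691742075 -2.17347476422
0.494660598794 1.50061182261 -2.30448164441
1.26691742723 2.17347475747 -1.21576655275
1.61319151616 1.61319151118 -1.61319151994
0.288337432486 -2.76752925535 0.254566190495
-1.08871509357 -2.46181219135 0.749226787506
-0.997007187112 -2.61019870286 7.16206241468e-09
-0.288337432505 -2.7675292568 -0.254566174785
-1.50061182904 -2.30448164167 -0.494660592049
-2.17347476061 -1.21576655048 -1.26691742401
1.67881416294 -2.01614421044 -0.96120035819
1.08871509355 -2.46181219561 -0.749226773531
1.61319151615 -1.61319152034 -1.61319151078
0.961200364821 -1.67881416843 -2.01614420271
-1.21576654636 -1.26691743309 -2.17347475763
-0.494660597654 -1.50061183569 -2.30448163613
-1.26691742663 -2.17347476437 -1.21576654104
-1.61319151537 -1.61319152033 -1.61319151158
-1.54027912889 -7.06871423739e-09 -2.49222398409
1.54027913013 -7.07906672939e-09 -2.49222398333
-1.54027913013 7.07906530204e-09 2.49222398333
-2.4922239837 1.54027912952 -4.98854348717e-09
-3.72726468838e-10 2.49222398808 1.54027912244
2.4922239837 -1.54027912952 4.98854212396e-09
2.49222398371 1.5402791295 -3.75526621848e-09
1.54027912889 7.06871238253e-09 2.49222398409
3.89478469325e-10 2.49222397934 -1.54027913658
-3.8947806599e-10 -2.49222397934 1.54027913658
-2.49222398371 -1.5402791295 3.75526553928e-09
3.72728539475e-10 -2.49222398808 -1.54027912244
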