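# 55|gyroelongated pentagonal cupola (J24)|Johnson
1.61803398918 4.22184904938e-09 0.23981257621
1.30901699248 0.95105651976 0.239812575735
0.499999996663 1.53884177007 0.239812576553
-0.500000003337 1.53884176762 0.239812578351
-1.30901699627 0.95105651335 0.239812580443
-1.61803398832 -3.70193499648e-09 0.23981258203
-1.30901699161 -0.95105651924 0.239812582505
-0.499999995801 -1.53884176955 0.239812581687
0.500000004199 -1.5388417671 0.239812579889
1.30901699713 -0.95105651283 0.239812577797
0.809016995108 0.26286555887 0.765543689499
-7.06150838009e-10 0.850650809182 0.765543690317
-0.809016993642 0.262865554908 0.765543692409
-0.499999996938 -0.68819096063 0.765543692884
0.500000003062 -0.688190958181 0.765543691086
1.53884176624 0.500000003093 -0.622584428049
0.95105651197 1.30901699603 -0.622584427869
-5.081535867e-09 1.61803398808 -0.622584426493
-0.95105652062 1.30901699137 -0.622584424448
-1.53884177093 0.499999995557 -0.622584422514
-1.53884176848 -0.500000004443 -0.62258442143
-0.95105651421 -1.30901699738 -0.62258442161
2.84224815601e-09 -1.61803398942 -0.622584422986
0.951056518381 -1.30901699272 -0.622584425031
1.53884176869 -0.499999996907 -0.622584426965
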