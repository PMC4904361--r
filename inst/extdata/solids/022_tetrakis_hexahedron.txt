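# 22|tetrakis hexahedron|Catalan
1.50851505044e-10 -0.9 -4.53097556419e-09
-0.599999997598 -0.59999999708 -0.600000005322
3.45180143691e-09 4.53097562783e-09 -0.9
0.600000002402 -0.599999996879 -0.600000000719
0.600000002201 0.600000003121 -0.599999994678
-1.50851545922e-10 0.9 4.53097545461e-09
0.599999997799 -0.60000000292 0.599999999281
0.599999997598 0.59999999708 0.600000005322
0.9 1.50851607998e-10 3.45180126277e-09
-0.599999997799 0.60000000292 -0.599999999281
-0.9 -1.50851514765e-10 -3.45180123105e-09
-0.600000002201 -0.600000003121 0.599999994678
-0.600000002402 0.599999996879 0.600000000719
-3.45180105386e-09 -4.53097553459e-09 0.9
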