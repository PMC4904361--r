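# 96|augmented truncated tetrahedron (J65)|Johnson
0.895668590839 0.188561805738 0.5185449715
0.188561813467 0.895668590739 0.518544968863
0.188561810088 0.188561812624 1.22565175312
0.89566858659 -0.51854497852 -0.188561806615
0.188561804968 -0.518544977778 -0.895668587366
0.188561801589 -1.22565175589 -0.188561803108
-0.518544968155 0.895668591481 -0.188561811888
-0.518544972404 0.188561807222 -0.895668590003
-1.22565175316 0.188561814108 -0.188561808381
-0.518544974913 -0.518544964749 1.22565175663
-0.518544979162 -1.22565174901 0.518544978514
-1.22565175653 -0.518544964006 0.518544975877
0.424264074553 1.13137084577 -0.424264073888
1.13137085193 0.424264060766 -0.424264071251
0.424264070304 0.424264061509 -1.131370852
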