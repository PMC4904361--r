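# 81|biaugmented triangular prism (J50)|Johnson
0.452877529717 -5.55111512313e-17 0.5
-0.413147874067 0.5 0.5
-0.413147874067 -0.5 0.5
0.452877529717 -5.55111512313e-17 -0.5
-0.413147874067 0.5 -0.5
-0.413147874067 -0.5 -0.5
0.373418218418 0.862372435696 4.33680868994e-17
0.373418218418 -0.862372435696 -1.21430643318e-17
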