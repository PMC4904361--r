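# 119|sphenomegacorona (J88)|Johnson
0 0.5 0.90337078377
0 -0.5 0.90337078377
0.594633335633 0.5 0.0993737712418
0.594633335633 -0.5 0.0993737712418
-0.594633335633 0.5 0.0993737712418
-0.594633335633 -0.5 0.0993737712418
0.5 0 -0.76146566314
-0.5 0 -0.76146566314
0 1.28310233883 0.281477925701
0 -1.28310233883 0.281477925701
0 0.854743082489 -0.622130588815
0 -0.854743082489 -0.622130588815
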