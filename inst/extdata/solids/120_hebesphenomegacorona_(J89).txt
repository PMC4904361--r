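# 120|hebesphenomegacorona (J89)|Johnson
0.542260094409 0.382322055667 0.888262573125
0.507178137045 -0.610522515984 0.774118309972
-0.456686982727 0.41378053959 0.921655699227
-0.491768940091 -0.579064032061 0.807511436073
0.730016639177 0.487955067416 -0.0882563190245
0.694934681813 -0.504889504235 -0.202400582178
-0.702163427657 0.533056769637 -0.040380940372
-0.737245385021 -0.459787802014 -0.154525203526
0.471072104881 0.0949387408073 -0.970574796207
-0.527874972255 0.12639722473 -0.937181670105
0.0454557628263 1.06684068231 0.354764957481
-0.0318154787571 -1.11999091194 0.103351707014
0.00763543910275 0.914161416149 -0.632786896751
-0.0509976727464 -0.745197730072 -0.82355827473
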