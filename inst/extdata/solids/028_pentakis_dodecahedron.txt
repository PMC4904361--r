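# 28|pentakis dodecahedron|Catalan
-0.87489167369 0.87489167067 0.874891672365
-0.776079653306 -1.2557232618 -8.52311552162e-11
-1.26337648461e-09 0.776079655321 1.25572326056
-2.38301881336e-09 1.41560446211 0.540712790055
0.874891670793 0.874891673646 0.874891672286
0.776079653306 1.2557232618 8.52311988591e-11
-0.776079657577 1.25572325916 1.54920438407e-10
-0.874891673769 0.874891670838 -0.874891672119
0.540712789856 1.05486964711e-09 -1.41560446219
1.25572326052 2.06119986692e-09 0.776079655385
-1.41560446308 0.540712787512 1.1526331131e-10
-2.43157338588e-09 1.41560446221 -0.540712789784
-1.37613723527e-09 0.776079655562 -1.25572326041
0.874891670715 0.874891673813 -0.874891672198
-0.540712789983 -7.84140805726e-10 -1.41560446214
1.26337582255e-09 -0.776079655321 -1.25572326056
-1.41560446124 -0.540712792327 1.18542847045e-11
-0.874891670793 -0.874891673646 -0.874891672286
-1.25572326052 -2.06120012252e-09 -0.776079655385
-1.25572326045 -2.20962252555e-09 0.776079655498
0.540712789983 7.84141790917e-10 1.41560446214
-0.540712789856 -1.05486983574e-09 1.41560446219
-0.874891670715 -0.874891673813 0.874891672198
2.38301865575e-09 -1.41560446211 -0.540712790055
0.87489167369 -0.87489167067 -0.874891672365
0.776079657577 -1.25572325916 -1.54921412112e-10
1.41560446308 -0.540712787512 -1.15263108005e-10
1.41560446124 0.540712792327 -1.18548813892e-11
1.25572326045 2.20962252844e-09 -0.776079655498
0.874891673769 -0.874891670838 0.874891672119
2.43157327413e-09 -1.41560446221 0.540712789784
1.37613671108e-09 -0.776079655562 1.25572326041
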