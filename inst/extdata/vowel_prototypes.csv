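vowel,f1,f2
i,280,2250
I,400,1920
y,270,1850
e,390,2200
E,550,1850
ae,690,1660
a,710,1100
A,750,940
V,620,1190
O,550,840
o,450,900
U,380,950
u,300,600
@,500,1500
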