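village,class,households,sampled,service,users
A,post-boom,38,34,charcoal,29
A,post-boom,38,34,firewood,33
A,post-boom,38,34,construction,19
A,post-boom,38,34,grass,9
A,post-boom,38,34,food,9
A,post-boom,38,34,medicine,2
A,post-boom,38,34,livestock,12
B,post-boom,29,25,charcoal,22
B,post-boom,29,25,firewood,25
B,post-boom,29,25,construction,18
B,post-boom,29,25,grass,12
B,post-boom,29,25,food,3
B,post-boom,29,25,medicine,5
B,post-boom,29,25,livestock,15
C,post-boom,63,51,charcoal,46
C,post-boom,63,51,firewood,49
C,post-boom,63,51,construction,25
C,post-boom,63,51,grass,30
C,post-boom,63,51,food,10
C,post-boom,63,51,medicine,11
C,post-boom,63,51,livestock,12
D,boom,42,36,charcoal,23
D,boom,42,36,firewood,31
D,boom,42,36,construction,21
D,boom,42,36,grass,18
D,boom,42,36,food,10
D,boom,42,36,medicine,7
D,boom,42,36,livestock,5
E,boom,58,42,charcoal,21
E,boom,58,42,firewood,42
E,boom,58,42,construction,24
E,boom,58,42,grass,5
E,boom,58,42,food,4
E,boom,58,42,medicine,5
E,boom,58,42,livestock,27
F,pre-boom,55,48,charcoal,42
F,pre-boom,55,48,firewood,48
F,pre-boom,55,48,construction,38
F,pre-boom,55,48,grass,9
F,pre-boom,55,48,food,6
F,pre-boom,55,48,medicine,6
F,pre-boom,55,48,livestock,29
G,pre-boom,27,24,charcoal,0
G,pre-boom,27,24,firewood,24
G,pre-boom,27,24,construction,14
G,pre-boom,27,24,grass,7
G,pre-boom,27,24,food,6
G,pre-boom,27,24,medicine,4
G,pre-boom,27,24,livestock,16
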