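class,village,service,trend
post-boom,A,charcoal,decline
post-boom,A,firewood,decline
post-boom,A,construction,decline
post-boom,A,food,no_change
post-boom,A,medicine,no_change
post-boom,A,grass,no_change
post-boom,B,charcoal,decline
post-boom,B,firewood,no_change
post-boom,B,construction,decline
post-boom,B,food,no_change
post-boom,B,medicine,no_change
post-boom,B,grass,no_change
post-boom,C,charcoal,decline
post-boom,C,firewood,no_change
post-boom,C,construction,decline
post-boom,C,food,no_change
post-boom,C,medicine,no_change
post-boom,C,grass,no_change
boom,D,charcoal,decline
boom,D,firewood,decline
boom,D,construction,decline
boom,D,food,no_change
boom,D,medicine,no_change
boom,D,grass,no_change
boom,E,charcoal,no_change
boom,E,firewood,no_change
boom,E,construction,decline
boom,E,food,no_change
boom,E,medicine,no_change
boom,E,grass,no_change
pre-boom,F,charcoal,no_change
pre-boom,F,firewood,no_change
pre-boom,F,construction,no_change
pre-boom,F,food,no_change
pre-boom,F,medicine,no_change
pre-boom,F,grass,no_change
pre-boom,G,charcoal,not_applicable
pre-boom,G,firewood,no_change
pre-boom,G,construction,no_change
pre-boom,G,food,no_change
pre-boom,G,medicine,no_change
pre-boom,G,grass,no_change
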