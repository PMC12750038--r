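target_id,supertarget
L1003,L1000
L1010,L1000
L1013,L1000
L3009,L3000
L3047,L3000
L3196,L3000
L3197,L3000
L3211,L3000
L3213,L3000
L3214,L3000
L3216,L3000
L3217,L3000
L3219,L3000
L3222,L3000
L3224,L3000
L3225,L3000
L3226,L3000
L3229,L3000
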