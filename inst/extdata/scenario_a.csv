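level_label,share,rate
EL1,0.40,750
EL2,0.25,550
EL3,0.25,450
EL4,0.10,300
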