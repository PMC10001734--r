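element,SH19,SH20,SH21,SH22
SH19,0.000,0.900,0.775,0.900
SH20,0.775,0.000,0.900,0.775
SH21,0.775,0.900,0.000,0.525
SH22,0.900,0.525,0.900,0.000
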