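element,SH19,SH20,SH21,SH22
SH19,0.000,0.324,0.306,0.315
SH20,0.342,0.000,0.360,0.297
SH21,0.289,0.305,0.000,0.306
SH22,0.306,0.306,0.314,0.000
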