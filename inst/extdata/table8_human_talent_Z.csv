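element,SH19,SH20,SH21,SH22
SH19,0.000,3.017,2.850,2.933
SH20,3.183,0.000,3.350,2.767
SH21,2.683,2.833,0.000,2.850
SH22,2.850,2.850,2.917,0.000
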