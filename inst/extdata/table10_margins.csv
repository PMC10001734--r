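element,D,R
SH19,16.532,16.394
SH20,17.222,16.377
SH21,15.898,16.973
SH22,16.256,16.164
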