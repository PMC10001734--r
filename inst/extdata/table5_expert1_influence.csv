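row,col,mu,nu
SH19,SH19,0,0
SH19,SH20,0.9,0.1
SH19,SH21,0.75,0.2
SH19,SH22,0.9,0.1
SH20,SH19,0.75,0.2
SH20,SH20,0,0
SH20,SH21,0.5,0.45
SH20,SH22,0.75,0.2
SH21,SH19,0.75,0.2
SH21,SH20,0.9,0.1
SH21,SH21,0,0
SH21,SH22,0.5,0.45
SH22,SH19,0.9,0.1
SH22,SH20,0.5,0.45
SH22,SH21,0.35,0.6
SH22,SH22,0,0
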