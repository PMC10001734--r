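row,col,mu,nu,pi
SH6,SH6,0.020,0.180,0.800
SH6,SH7,0.105,0.195,0.698
SH6,SH8,0.123,0.209,0.666
SH7,SH6,0.132,0.172,0.695
SH7,SH7,0.020,0.180,0.800
SH7,SH8,0.100,0.206,0.692
SH8,SH6,0.174,0.163,0.662
SH8,SH7,0.114,0.188,0.697
SH8,SH8,0.020,0.180,0.800
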