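expert,label,mu,nu,pi,weight
DM1,very relevant,0.9,0.05,0.05,0.171429
DM2,very relevant,0.9,0.05,0.05,0.171429
DM3,very relevant,0.9,0.05,0.05,0.171429
DM4,very relevant,0.9,0.05,0.05,0.171429
DM5,very relevant,0.9,0.05,0.05,0.171429
DM6,relevant,0.75,0.2,0.05,0.142857
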