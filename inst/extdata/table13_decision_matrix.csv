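subcriterion,D1,D2,D3,weight,direction
SH1,80,100,90,0.028,benefit
SH2,0,0,0,0.029,cost
SH3,1,1,1,0.032,benefit
SH4,1,1,1,0.026,benefit
SH5,2200,2800,3000,0.029,benefit
SH6,100,100,95,0.038,benefit
SH7,98,95,95,0.039,benefit
SH8,0,0.5,1,0.043,cost
SH9,1,1,1,0.039,benefit
SH10,99,100,95,0.039,benefit
SH11,0,0,0,0.039,benefit
SH12,90,60,120,0.019,cost
SH13,90,60,60,0.020,cost
SH14,15,15,20,0.016,cost
SH15,5,60,5,0.019,cost
SH16,1,1,1,0.019,benefit
SH17,1,1,1,0.019,benefit
SH18,0,0,0,0.022,benefit
SH19,6,3,8,0.029,cost
SH20,30,4,36,0.035,cost
SH21,60,80,90,0.037,benefit
SH22,26,23,20,0.036,cost
SH23,68,85,100,0.025,cost
SH24,95,95,90,0.028,benefit
SH25,90,95,90,0.025,benefit
SH26,40,90,70,0.031,cost
SH27,5,5,7,0.024,cost
SH28,85,91,90,0.026,benefit
SH29,60,60,65,0.025,cost
SH30,0.1,1,0.5,0.025,cost
SH31,5,5,5,0.024,cost
SH32,0,0,0,0.028,cost
SH33,0,0,0,0.029,cost
SH34,0,0,0,0.032,cost
SH35,0,0.002,0.001,0.030,cost
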