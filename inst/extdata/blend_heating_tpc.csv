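blend,condition,measure,mean,sd,n
RBc,unheated,tpc,5.41,0.10,4
RBc,170C,tpc,7.41,0.14,4
RBc,200C,tpc,10.74,0.17,4
RMt,unheated,tpc,3.78,0.14,4
RMt,170C,tpc,8.99,0.10,4
RMt,200C,tpc,11.74,0.14,4
RP,unheated,tpc,6.45,0.30,4
RP,170C,tpc,10.54,0.13,4
RP,200C,tpc,14.53,0.23,4
BcH,unheated,tpc,4.98,0.15,4
BcH,170C,tpc,7.84,0.17,4
BcH,200C,tpc,12.74,0.06,4
HMtR,unheated,tpc,4.62,0.16,4
HMtR,170C,tpc,9.57,0.17,4
HMtR,200C,tpc,14.98,0.27,4
LRb,unheated,tpc,1.84,0.14,4
LRb,170C,tpc,4.01,0.11,4
LRb,200C,tpc,7.96,0.04,4
HRbR,unheated,tpc,2.54,0.04,4
HRbR,170C,tpc,5.29,0.13,4
HRbR,200C,tpc,7.88,0.23,4
PLRb,unheated,tpc,3.41,0.04,4
PLRb,170C,tpc,7.05,0.14,4
PLRb,200C,tpc,13.45,0.00,4
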