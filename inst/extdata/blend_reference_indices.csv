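blend,pufa_sfa,ia,it,hh,civ,civ_sd,omega_ratio
RBc,4.09,0.09,0.15,11.57,119.56,0.20,4.84
RMt,3.21,0.07,0.16,13.36,116.51,1.55,5.25
RP,3.37,0.09,0.18,10.68,116.83,0.14,5.02
BcH,5.77,0.10,0.14,10.08,145.03,0.49,4.93
HMtR,3.48,0.08,0.16,13.01,120.75,1.55,5.24
LRb,2.43,0.19,0.27,5.20,115.00,0.02,5.14
HRbR,3.07,0.13,0.20,7.34,117.17,0.08,5.13
PLRb,2.98,0.16,0.26,6.33,124.90,0.09,5.20
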