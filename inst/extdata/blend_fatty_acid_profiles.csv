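blend,acid,percent,sd
RBc,C16:0,7.76,0.13
RBc,C16:1,0.18,0.03
RBc,C18:0,2.21,0.04
RBc,C18:1,48.52,0.08
RBc,C18:2,34.17,0.26
RBc,C18:3,7.07,0.06
RBc,C20:0,0.10,0.01
RBc,C20:1,nd,nd
RBc,C22:0,nd,nd
RMt,C16:0,6.52,0.05
RMt,C16:1,0.12,0.01
RMt,C18:0,3.88,0.05
RMt,C18:1,46.23,1.45
RMt,C18:2,34.36,1.09
RMt,C18:3,6.55,0.34
RMt,C20:0,1.55,0.07
RMt,C20:1,nd,nd
RMt,C22:0,0.80,0.01
RP,C16:0,8.23,0.24
RP,C16:1,0.15,0.01
RP,C18:0,3.57,0.04
RP,C18:1,47.54,0.73
RP,C18:2,33.65,0.46
RP,C18:3,6.70,0.01
RP,C20:0,0.14,0.01
RP,C20:1,nd,nd
RP,C22:0,0.03,0.01
BcH,C16:0,8.56,0.34
BcH,C16:1,0.12,0.03
BcH,C18:0,2.69,0.04
BcH,C18:1,18.46,0.08
BcH,C18:2,56.40,0.54
BcH,C18:3,11.43,0.16
BcH,C20:0,0.37,0.01
BcH,C20:1,1.84,0.07
BcH,C22:0,0.13,0.02
HMtR,C16:0,6.65,0.24
HMtR,C16:1,0.11,0.00
HMtR,C18:0,3.96,0.07
HMtR,C18:1,41.22,1.10
HMtR,C18:2,38.06,0.87
HMtR,C18:3,7.27,0.38
HMtR,C20:0,1.60,0.13
HMtR,C20:1,0.31,0.00
HMtR,C22:0,0.82,0.03
LRb,C16:0,15.64,0.06
LRb,C16:1,0.13,0.03
LRb,C18:0,1.79,0.12
LRb,C18:1,37.49,0.81
LRb,C18:2,36.67,0.95
LRb,C18:3,7.14,0.38
LRb,C20:0,0.57,0.00
LRb,C20:1,0.55,0.03
LRb,C22:0,0.01,0.00
HRbR,C16:0,11.61,0.09
HRbR,C16:1,0.14,0.02
HRbR,C18:0,1.75,0.08
HRbR,C18:1,42.88,0.33
HRbR,C18:2,35.47,0.02
HRbR,C18:3,6.92,0.16
HRbR,C20:0,0.41,0.03
HRbR,C20:1,0.80,0.00
HRbR,C22:0,0.03,0.00
PLRb,C16:0,12.91,0.07
PLRb,C16:1,0.11,0.00
PLRb,C18:0,4.63,0.10
PLRb,C18:1,28.21,0.05
PLRb,C18:2,44.93,0.05
PLRb,C18:3,8.64,0.05
PLRb,C20:0,0.37,0.01
PLRb,C20:1,0.16,0.01
PLRb,C22:0,0.05,0.00
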