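blend,water_ppm,water_sd,t1_ms,t1_sd,t2_ms,t2_sd,tau_c_s,oit_min
RBc,536.5,4.9,106.73,0.33,69.97,1.22,4.9298e-9,65.33
RMt,471.7,6.6,102.91,0.43,72.11,1.56,4.4037e-9,54.72
RP,823.5,10.5,105.40,0.38,63.91,1.40,5.5434e-9,75.40
BcH,516.1,18.1,118.90,0.33,81.54,1.42,4.5746e-9,32.60
HMtR,341.4,14.6,106.23,0.34,71.61,1.41,4.7103e-9,46.95
LRb,176.4,4.7,102.51,0.28,74.78,1.45,4.0809e-9,44.93
HRbR,556.6,20.9,102.74,0.29,66.63,1.23,5.0148e-9,48.13
PLRb,458.6,13.6,108.95,0.32,69.44,1.34,5.1513e-9,52.20
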