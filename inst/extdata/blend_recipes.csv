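blend,oil,mass_fraction
RBc,rapeseed,0.60
RBc,black_cumin,0.40
RMt,rapeseed,0.50
RMt,milk_thistle,0.50
RP,rapeseed,0.58
RP,pumpkin_seed,0.42
BcH,black_cumin,0.40
BcH,hemp,0.60
HMtR,hemp,0.10
HMtR,milk_thistle,0.50
HMtR,rapeseed,0.40
LRb,linseed,0.11
LRb,rice_bran,0.89
HRbR,hemp,0.15
HRbR,rice_bran,0.55
HRbR,rapeseed,0.30
PLRb,pumpkin_seed,0.60
PLRb,linseed,0.15
PLRb,rice_bran,0.25
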