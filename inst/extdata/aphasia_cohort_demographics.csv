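id,sex,mpo,age,wab_aq,ca_bat,bat_sync
COL1,F,12,47,49.1,-2.5,0.93
COL3,F,15,55,55,-0.6,0.92
COL4,F,37,65,65.6,-3.8,0.98
COL6,M,17,53,27.1,-1.4,0.89
COL7,F,24,56,43.7,-1.9,0.79
COL9,M,27,58,20.4,-2.0,0.86
COL10,F,24,42,64.2,-4,0.95
COL12,M,42,31,37.7,-3.5,0.64
COL13,M,14,78,39.5,-2.6,0.84
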