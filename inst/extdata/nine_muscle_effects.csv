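muscle,IC,FF,HO,TO
RF,1,0.49,0.25,0.29
VM,1,0.35,0.27,0.33
VL,1,0.54,0.56,0.53
TA,0.81,0.18,0.21,1
SL,0.21,0.94,1,0.21
ST,0.74,0.24,0.23,1
BF,1,0.88,0.96,0.87
GM,0.16,0.61,1,0.16
GL,0.44,0.78,1,0.18
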