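sheep,rout_bolus,rout_bolus_sd,rout_cpi
A,NA,NA,NA
B,83.0,9.3,71.6
C,38.4,7.1,79.1
D,39.8,3.5,78.4
E,NA,NA,NA
F,45.3,2.5,69.9
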