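sheep,itp,itp_sd,itp_amp,itp_amp_sd,icp,icp_sd,icp_amp,icp_amp_sd,abp,abp_sd,abp_amp,abp_amp_sd,cvp,cvp_sd,cvp_amp,cvp_amp_sd
A,0.4,0.2,0.3,0.0,2.2,0.1,0.4,0.1,84.6,1.5,15.3,0.4,4.6,0.1,4.7,0.2
B,23.9,1.2,3.2,0.1,20.7,0.8,3.2,0.3,91.8,1.0,18.0,0.8,5.3,0.2,3.4,0.0
C,6.2,0.9,1.2,0.0,6.5,0.2,3.2,0.1,65.9,0.7,37.4,0.4,4.7,0.9,2.4,0.0
D,0.0,0.3,1.1,0.0,10.0,0.0,1.4,0.0,83.8,2.8,12.7,0.2,2.9,0.3,0.8,0.0
E,5.6,4.5,1.7,0.1,16.7,0.0,0.4,0.0,89.8,0.4,15.8,0.2,1.3,0.0,4.9,0.1
F,27.2,0.2,5.7,0.1,27.2,0.3,6.9,0.2,64.4,0.7,26.5,0.3,3.9,0.1,4.7,0.1
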