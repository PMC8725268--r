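sheep,d_itp,d_itp_sd,d_itp_amp,d_itp_amp_sd,d_icp,d_icp_sd,d_icp_amp,d_icp_amp_sd,d_abp,d_abp_sd,d_abp_amp,d_abp_amp_sd,d_cvp,d_cvp_sd,d_cvp_amp,d_cvp_amp_sd
A,24.9,2.3,2.5,0.4,1.9,0.3,1.4,0.3,3.2,0.9,1.1,0.3,0.0,0.1,0.3,0.1
B,24.4,0.8,2.7,0.2,24.2,1.0,1.1,0.2,2.3,0.8,1.3,0.7,0.0,0.2,0.1,0.1
C,14.1,2.0,2.1,0.4,13.8,1.1,1.3,0.3,0.8,0.9,1.0,0.4,-0.0,0.1,0.0,0.1
D,14.0,0.5,2.6,0.4,9.8,0.7,1.2,0.2,4.1,0.5,1.4,0.3,0.0,0.1,0.1,0.1
E,42.2,0.5,2.4,0.3,2.3,0.4,1.3,0.2,0.7,0.9,0.7,0.1,0.1,0.1,0.3,0.1
F,13.8,0.5,1.9,0.1,13.5,0.5,1.0,0.2,8.4,0.9,2.4,0.4,0.6,0.2,0.3,0.2
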