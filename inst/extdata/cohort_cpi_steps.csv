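step,itp,itp_sd,itp_amp,itp_amp_sd,icp,icp_sd,icp_amp,icp_amp_sd,abp,abp_sd,abp_amp,abp_amp_sd,cvp,cvp_sd,cvp_amp,cvp_amp_sd
1,20.4,3.8,7.1,1.5,20.7,4.3,5.9,1.1,81.2,9.8,22.4,1.5,4.7,1.0,7.7,0.8
2,22.9,4.1,8.8,1.2,23.4,4.5,6.2,1.1,81.7,9.8,24.0,1.3,4.8,1.1,7.7,0.8
3,26.1,4.4,8.6,1.4,26.8,4.5,6.7,1.2,81.9,10.0,23.7,1.5,6.2,1.3,7.8,0.9
4,29.3,4.5,8.3,2.0,29.9,4.3,7.6,1.5,81.7,9.5,24.2,2.4,7.1,2.1,7.9,0.9
5,32.2,4.0,8.9,2.1,32.7,3.8,8.0,1.7,83.0,8.9,26.7,3.1,7.5,2.2,8.3,1.1
6,35.0,3.9,9.6,2.1,36.2,4.2,8.4,1.9,85.4,7.8,30.1,2.8,7.9,2.4,8.4,1.2
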