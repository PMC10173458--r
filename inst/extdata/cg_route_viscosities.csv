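system,route,mu_m,uncertainty
P-S,sd_rot_vs_R,6.6,NA
P-M,sd_rot_vs_R,4.4,0.3
P-L,sd_rot_vs_R,5.5,0.5
S-set,sd_rot_vs_R_corrected,4.7,0.1
P-set,sd_lat_vs_R_corrected,6.9,NA
S-set,sd_lat_vs_R_corrected,4.6,NA
P-set,lat_vs_boxsize,9.7,1.1
S-4,lat_vs_boxsize,7.5,0.3
S-3,rot_vs_boxsize,13.3,4.6
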