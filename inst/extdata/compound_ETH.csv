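parameter,value
name,ETH
dose_mg,1974.6
mw_free,204.31
mw_salt,277.23
bp_ratio,0.94
fu,0.75
vdss_L_per_kg,6.1
peff_1e4_cm_s,0.67
cl_iv_L_per_h,41.9
cl_r_L_per_h,32.4
kp_Lung,7.92
kp_Adipose,1.22
kp_Muscle,9.14
kp_Liver,8.65
kp_Spleen,8.75
kp_Heart,7.48
kp_Brain,8.9
kp_Kidney,8.07
kp_Skin,6.26
kp_ReproOrg,8.07
kp_RedMarrow,3.15
kp_YellowMarrow,3.15
kp_RestOfBody,46
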