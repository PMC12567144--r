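parameter,value
name,RIF
dose_mg,300
mw_free,822.94
mw_salt,822.94
bp_ratio,0.67
fu,0.15
vdss_L_per_kg,0.42
peff_1e4_cm_s,1.3
cl_iv_L_per_h,8.307
cl_r_L_per_h,1.5
kp_Lung,0.14
kp_Adipose,0.28
kp_Muscle,0.15
kp_Liver,0.29
kp_Spleen,0.19
kp_Heart,0.14
kp_Brain,0.16
kp_Kidney,0.24
kp_Skin,0.19
kp_ReproOrg,0.24
kp_RedMarrow,0.3
kp_YellowMarrow,0.3
kp_RestOfBody,5
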