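parameter,value
name,MOX
dose_mg,200
mw_free,401.44
mw_salt,437.9
bp_ratio,1.14
fu,0.52
vdss_L_per_kg,1.9
peff_1e4_cm_s,1.45
cl_iv_L_per_h,13.15
cl_r_L_per_h,2.54
kp_Lung,4.9
kp_Adipose,0.52
kp_Muscle,2
kp_Liver,5.69
kp_Spleen,4.01
kp_Heart,2.88
kp_Brain,0.64
kp_Kidney,6.26
kp_Skin,1.74
kp_ReproOrg,6.33
kp_RedMarrow,0.75
kp_YellowMarrow,0.75
kp_RestOfBody,17.55
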