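tissue,volume_L_per_73kg,flow_fraction_of_co
Lung,1.17,NA
Adipose,18.2,0.05
Muscle,29,0.17
Liver,1.8,0.225
Spleen,0.19,0.03
Heart,0.33,0.04
Brain,1.45,0.12
Kidney,0.31,0.19
Skin,3.3,0.05
ReproOrg,0.035,5e-04
RedMarrow,1.17,0.03
YellowMarrow,2.48,0.01
RestOfBody,4.48880952380952,0.0845
co_L_per_h_73kg,390,NA
blood_volume_L_73kg,5.6,NA
venous_fraction,0.7,NA
hematocrit,0.45,NA
reference_weight_kg,73,NA
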