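factor,category,arm_A,arm_B
gender,male,3,2
gender,female,7,8
age_band,<80,6,9
age_band,>=80,4,1
fracture_type,proximal_femur,0,2
fracture_type,distal_forearm,4,4
fracture_type,clinical_vertebral,0,0
fracture_type,other,6,4
time_since_fracture,0-3_months,5,7
time_since_fracture,>3_months,5,3
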