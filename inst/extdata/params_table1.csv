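factor_id,level_id,is_reference,consensus_rr,us_prevalence,nhs_prevalence,observed_rr,observed_rr_mv,applicability
bmi,lt25,1,1.00,0.500,0.443,1.00,1.00,age<60
bmi,25to29,0,2.25,0.200,0.275,1.21,1.02,age<60
bmi,ge29,0,5.00,0.300,0.282,2.10,1.47,age<60
waist,le35in,1,1.00,0.547,0.851,1.00,1.00,age>=60
waist,gt35in,0,2.25,0.453,0.149,1.47,1.23,age>=60
smoking,never,1,1.00,0.480,0.453,1.00,1.00,always
smoking,current_ge25,0,5.00,0.050,0.019,2.12,2.73,always
smoking,current_15to24,0,2.25,0.100,0.046,2.48,3.15,always
smoking,current_le14,0,1.30,0.090,0.050,2.61,3.13,always
smoking,quit_lt2y,0,1.30,0.060,0.019,1.80,1.84,always
smoking,quit_2to10y,0,1.30,0.060,0.098,1.44,1.44,always
smoking,quit_10to20y,0,1.00,0.060,0.106,1.10,1.13,always
smoking,quit_ge20y,0,1.00,0.100,0.209,1.11,1.09,always
secondhand_smoke,rare,1,1.00,0.900,0.674,1.00,1.00,not_current_smoker
secondhand_smoke,regular,0,1.30,0.100,0.326,1.03,1.20,not_current_smoker
multivitamin,lt5wk,1,1.00,0.400,0.579,1.00,1.00,always
multivitamin,ge5wk,0,0.80,0.600,0.421,1.01,1.02,always
physical_activity,lt3hwk,1,1.00,0.810,0.787,1.00,1.00,always
physical_activity,ge3hwk,0,0.55,0.190,0.213,0.79,0.85,always
high_blood_pressure,no,1,1.00,0.725,0.745,1.00,1.00,always
high_blood_pressure,yes,0,2.25,0.275,0.255,2.05,1.51,always
diabetes,no,1,1.00,0.919,0.961,1.00,1.00,always
diabetes,yes,0,2.25,0.081,0.039,4.41,3.20,always
cholesterol,le159,1,1.00,0.140,0.071,1.00,1.00,always
cholesterol,160to199,0,1.30,0.350,0.252,0.83,0.86,always
cholesterol,200to239,0,2.25,0.300,0.478,1.15,0.98,always
cholesterol,240to299,0,5.00,0.150,0.171,1.48,1.26,always
cholesterol,ge300,0,7.00,0.060,0.028,2.56,2.00,always
family_history,no,1,1.00,0.540,0.673,1.00,1.00,always
family_history,yes,0,2.25,0.460,0.327,1.43,1.30,always
fish,lt2wk,1,1.00,0.650,0.750,1.00,1.00,always
fish,ge2wk,0,0.55,0.350,0.250,0.91,0.90,always
fruits_vegetables,lt5day,1,1.00,0.740,0.427,1.00,1.00,always
fruits_vegetables,ge5day,0,0.55,0.260,0.573,1.08,1.11,always
whole_grains,lt3day,1,1.00,0.890,0.935,1.00,1.00,always
whole_grains,ge3day,0,0.55,0.110,0.065,0.83,0.79,always
nuts,lt3wk,1,1.00,0.880,0.766,1.00,1.00,always
nuts,ge3wk,0,0.80,0.120,0.234,1.06,0.99,always
saturated_fat,lt2day,1,1.00,0.290,0.748,1.00,1.00,always
saturated_fat,ge2day,0,1.30,0.710,0.252,1.18,1.08,always
trans_fat,lt5wk,1,1.00,0.600,0.369,1.00,1.00,always
trans_fat,ge5wk,0,1.30,0.400,0.631,1.04,1.00,always
unsaturated_fat,lt5wk,1,1.00,0.850,0.614,1.00,1.00,always
unsaturated_fat,ge5wk,0,0.80,0.150,0.387,0.91,0.94,always
alcohol,none,1,1.00,0.890,0.843,1.00,1.00,always
alcohol,ge1day,0,0.55,0.110,0.157,0.82,0.79,always
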