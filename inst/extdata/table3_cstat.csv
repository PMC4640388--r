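stratum,n,cases,c_printed,c_lo_printed,c_hi_printed
overall,55802,1165,0.62,0.60,0.63
age_le55,14918,124,0.71,0.69,0.74
age_56_60,12469,160,0.66,0.65,0.68
age_61_65,11350,244,0.62,0.61,0.64
age_66_70,11222,386,0.62,0.61,0.64
age_gt70,5843,251,0.59,0.58,0.61
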