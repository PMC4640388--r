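stratum,category,n,cases,or_printed,or_lo_printed,or_hi_printed
overall,very_much_below_average,23140,290,0.42,0.32,0.55
overall,much_below_average,14941,308,0.70,0.53,0.91
overall,below_average,7278,173,0.81,0.61,1.07
overall,about_average,2321,68,1.00,NA,NA
overall,above_average,4369,166,1.31,0.98,1.74
overall,much_above_average,2836,115,1.40,1.03,1.90
overall,very_much_above_average,917,45,1.71,1.16,2.51
age_lt60,very_much_below_average,11390,56,0.39,0.22,0.71
age_lt60,much_below_average,6923,62,0.72,0.40,1.29
age_lt60,below_average,3271,38,0.94,0.51,1.73
age_lt60,about_average,1129,14,1.00,NA,NA
age_lt60,above_average,2156,47,1.78,0.97,3.24
age_lt60,much_above_average,1586,40,2.06,1.12,3.81
age_lt60,very_much_above_average,711,26,3.02,1.57,5.83
age_ge60,very_much_below_average,11750,234,0.43,0.32,0.58
age_ge60,much_below_average,8018,246,0.67,0.49,0.90
age_ge60,below_average,4007,135,0.74,0.53,1.01
age_ge60,about_average,1192,54,1.00,NA,NA
age_ge60,above_average,2213,119,1.20,0.86,1.67
age_ge60,much_above_average,1250,75,1.35,0.94,1.93
age_ge60,very_much_above_average,206,19,2.14,1.24,3.69
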