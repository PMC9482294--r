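variable,level,e_coef,e_pct,c_coef,c_pct
total,,0.04483,81.12,0.01043,18.88
sex_of_child,male,-0.00000,-0.00,0.00010,0.18
sex_of_child,female,-0.00000,-0.00,-0.00010,-0.18
size_at_birth,large,0.00010,0.19,-0.00098,-1.77
size_at_birth,average,0.00003,0.06,-0.00023,-0.41
size_at_birth,smaller,-0.00019,-0.35,0.00052,0.94
twin_status,single,0.00004,0.08,0.00141,2.55
twin_status,multiple,0.00004,0.08,-0.00003,-0.05
mothers_age,15-19,0.00085,1.54,-0.00019,-0.34
mothers_age,20-24,0.00082,1.49,-0.00165,-2.98
mothers_age,25-29,-0.00059,-1.07,-0.00114,-2.06
mothers_age,30-34,0.00009,0.16,-0.00035,-0.64
mothers_age,35-39,0.00009,0.16,0.00052,0.94
mothers_age,40-44,-0.00048,-0.86,0.00033,0.59
mothers_age,45-49,-0.00048,-0.87,0.00028,0.50
education,none,0.00186,3.37,0.00028,0.51
education,primary,0.00009,0.16,-0.00036,-0.65
education,secondary,-0.00105,-1.89,-0.00014,-0.26
education,higher,0.00102,1.85,0.00002,0.03
working_status,no,0.00001,0.03,-0.00037,-0.66
working_status,yes,0.00001,0.03,0.00073,1.33
anc,none,0.00353,6.39,0.00088,1.59
anc,1-3,-0.00131,-2.37,-0.00097,-1.76
anc,4+,0.00521,9.42,-0.00187,-3.39
marital_status,married,-0.00015,-0.28,0.00207,3.75
marital_status,cohabiting,-0.00015,-0.28,-0.00040,-0.73
religion,none_other,-0.00013,-0.23,0.00012,0.22
religion,christianity,0.00020,0.37,-0.00032,-0.57
religion,islamic,0.00009,0.16,0.00035,0.63
religion,traditional,0.00015,0.26,-0.00012,-0.21
insurance,no,0.00086,1.56,0.00049,0.88
insurance,yes,0.00086,1.56,-0.00002,-0.04
parity,1,0.00186,3.36,-0.00014,-0.26
parity,2,0.00056,1.02,0.00006,0.12
parity,3,-0.00035,-0.64,-0.00019,-0.34
parity,4+,0.00502,9.08,0.00093,1.68
partner_education,none,0.00167,3.02,0.00043,0.77
partner_education,primary,-0.00051,-0.92,0.00036,0.66
partner_education,secondary,-0.00034,-0.62,-0.00041,-0.74
partner_education,higher,0.00065,1.17,-0.00002,-0.04
decides_health_care,respondent,-0.00014,-0.25,-0.00067,-1.20
decides_health_care,respondent_partner,-0.00004,-0.08,-0.00023,-0.41
decides_health_care,partner,0.00057,1.04,-0.00078,-1.41
decides_health_care,other,-0.00003,-0.05,0.00005,0.09
decides_purchases,respondent,0.00027,0.48,0.00045,0.81
decides_purchases,respondent_partner,0.00028,0.50,0.00053,0.95
decides_purchases,partner,-0.00036,-0.64,0.00166,3.00
decides_purchases,other,-0.00000,-0.00,-0.00010,-0.19
decides_visits,respondent,0.00034,0.61,0.00155,2.80
decides_visits,respondent_partner,0.00034,0.62,0.00200,3.61
decides_visits,partner,-0.00042,-0.75,0.00115,2.07
decides_visits,other,0.00004,0.06,-0.00014,-0.26
household_head,male,0.00001,0.02,0.00098,1.77
household_head,female,0.00001,0.02,-0.00015,-0.27
tv_frequency,not_at_all,0.00088,1.60,-0.00038,-0.69
tv_frequency,less_than_weekly,0.00011,0.19,0.00028,0.52
tv_frequency,at_least_weekly,-0.00016,-0.28,-0.00027,-0.49
radio_frequency,not_at_all,0.00036,0.65,0.00088,1.59
radio_frequency,less_than_weekly,0.00003,0.05,0.00003,0.05
radio_frequency,at_least_weekly,0.00017,0.32,-0.00059,-1.06
newspaper_frequency,not_at_all,0.00062,1.12,-0.00011,-0.21
newspaper_frequency,less_than_weekly,0.00005,0.08,0.00005,0.09
newspaper_frequency,at_least_weekly,0.00028,0.50,-0.00002,-0.04
wealth,poorest,0.00630,11.40,0.00039,0.71
wealth,poorer,0.00234,4.23,0.00036,0.65
wealth,middle,0.00027,0.48,-0.00039,-0.71
wealth,richer,0.00147,2.66,-0.00013,-0.23
wealth,richest,0.01127,20.38,0.00002,0.03
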