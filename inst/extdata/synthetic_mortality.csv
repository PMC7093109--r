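country,sex,age_lo,age_hi,cause,year,deaths,population
Synthia,male,35,70,lung_cancer,2000,980,1000000
Synthia,male,35,70,coronary_heart_disease,2000,6400,1000000
Synthia,male,35,70,other_cancers,2000,3720,1000000
Synthia,male,35,70,copd,2000,1640,1000000
Synthia,male,35,70,all_causes,2000,20000,1000000
Synthia,female,35,70,lung_cancer,2000,630,1000000
Synthia,female,35,70,coronary_heart_disease,2000,4650,1000000
Synthia,female,35,70,other_cancers,2000,2875,1000000
Synthia,female,35,70,copd,2000,937.5,1000000
Synthia,female,35,70,all_causes,2000,15000,1000000
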