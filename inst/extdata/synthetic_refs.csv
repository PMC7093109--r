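sex,age_lo,age_hi,never_rate_population,smoker_rate_study,never_rate_study
male,35,70,14,294,14
female,35,70,12,216,12
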