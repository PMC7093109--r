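cause,sex,age_lo,age_hi,rr_current,rr_former
lung_cancer,male,35,70,21.0,3.3
other_cancers,male,35,70,1.8,1.3
coronary_heart_disease,male,35,70,3.0,1.2
copd,male,35,70,25.0,7.0
lung_cancer,female,35,70,18.0,3.0
other_cancers,female,35,70,1.6,1.2
coronary_heart_disease,female,35,70,3.2,1.3
copd,female,35,70,22.0,6.5
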