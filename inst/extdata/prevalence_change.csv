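country,metric,y2000,y2015
US,prevalence_percent,23.1,15.2
UK,prevalence_percent,27,17.8
Canada,prevalence_percent,24.4,13
US,cigarettes_per_day,18.1,14.2
UK,cigarettes_per_day,13.8,11.3
Canada,cigarettes_per_day,16.8,13.8
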