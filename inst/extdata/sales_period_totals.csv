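country,start_year,end_year,total_sticks
US,1940,2000,3.26e+13
UK,1940,2000,7e+12
Canada,1940,2000,3.2e+12
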