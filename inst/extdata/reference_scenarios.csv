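strategy,org,cost_millions,crc_detected,crc_prevented,crc_deaths_prevented,screens_thousands,colonoscopies_thousands
previous_year,centralized,7.8,140,69,35,85.3,3.1
previous_year,hybrid,8.4,150,74,37,85.3,3.3
previous_year,regional,9.4,158,78,39,89.8,3.5
at_least_once,centralized,9.9,181,91,46,113.1,4.0
at_least_once,hybrid,10.6,194,98,50,113.1,4.3
at_least_once,regional,11.9,204,104,52,119.0,4.5
everyone,centralized,17.5,215,107,54,132.0,4.8
everyone,hybrid,18.7,232,115,58,132.0,5.1
everyone,regional,20.5,244,121,61,139.3,5.4
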