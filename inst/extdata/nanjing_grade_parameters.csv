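grade,cost_coeff,income_coeff,bed_coeff,min_share
AAAAA,11250,7916,777.6,0.15
AAAA,7200,5480,265.4,0.15
AAA,3600,2771.428571,168.1428571,0.15
AA,1875,2333.333333,74.33333333,0.15
A,375,750,35,0.15
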