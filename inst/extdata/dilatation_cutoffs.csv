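group,sex,age_min,age_max,threshold_g_m2
edv_index,M,0,60,101
edv_index,M,60,Inf,95
edv_index,F,0,60,96
edv_index,F,60,Inf,87
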