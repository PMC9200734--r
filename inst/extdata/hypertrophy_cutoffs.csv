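group,sex,age_min,age_max,threshold_g_m2
cmr_based,M,0,60,92
cmr_based,M,60,Inf,91
cmr_based,F,0,60,78
cmr_based,F,60,Inf,79
ase_te_al,M,0,Inf,103
ase_te_al,F,0,Inf,89
ase_dev,M,0,Inf,116
ase_dev,F,0,Inf,96
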