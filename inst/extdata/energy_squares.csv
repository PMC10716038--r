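label,kd_T,sd_T,kd_K,sd_K,kd_T_star,sd_T_star,kd_K_star,sd_K_star,units
THD1:KIND2:beta3-CT,108,12,9,2,102,40,54,27,uM
THD1-K402E:KIND2:beta3-CT,34,2,9,2,76,11,16,1,uM
THD1:KIND2-Y13A:beta3-CT,108,12,9,0,218,55,21,3,uM
THD1:KIND2:beta1-spacer-CT,181,11,5,1,279,36,6,3,uM
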