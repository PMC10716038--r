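label,value_uM,sd_uM,n,assay,notes
THD1 vs beta3-CT,108,12,0,MST,free tail
THD2 vs beta3-CT,39,3,0,MST,free tail
KIND2 vs beta3-CT,9,2,0,MST,free tail
KIND2 vs beta3-CT + THD1,54,27,0,MST,apparent; THD1 near saturation
KIND2 vs beta3-CT + TLN1-F3,120,1,0,MST,apparent
KIND2 vs beta3-CT + THD2,27,5,0,MST,apparent
KIND2 vs beta3-CT + TLN2-F3,47,14,0,MST,apparent
THD1 vs beta3-CT + KIND2,102,40,0,MST,apparent; KIND2 near saturation
THD1-K402E vs beta3-CT,34,2,0,MST,contact-breaking talin substitution
KIND2 vs beta3-CT + THD1-K402E,16,1,0,MST,apparent
THD1 vs beta3-CT (Y13A series),105,20,0,MST,free tail
THD1 vs beta3-CT + KIND2-Y13A,218,55,0,MST,apparent
KIND2-Y13A vs beta3-CT,9,0,0,MST,free tail
KIND2-Y13A vs beta3-CT + THD1,21,3,0,MST,apparent
F3-dKIND2 fusion vs beta1-CT-Y783A,4.8,1.1,0,MST global fit,kindlin-site-only curve
F3-dKIND2 fusion vs beta1-CT-Y795A,470,140,0,MST global fit,talin-site-only curve
F3-dKIND2 fusion vs beta1-CT (kindlin component),2.9,0.4,0,MST two-component fit,concentrations up to 5 uM
F3-dKIND2 fusion vs beta1-CT (talin component),25,3,0,MST two-component fit,concentrations above 5 uM
F3-dKIND2-Y13A fusion vs beta1-CT (talin component),16,1,0,MST two-component fit,concentrations above 5 uM
THD1 vs beta1-spacer-CT,181,11,0,MST,free tail
KIND2 vs beta1-spacer-CT,5,1,0,MST,free tail
THD1 vs beta1-spacer-CT + KIND2,279,36,0,MST,apparent
KIND2 vs beta1-spacer-CT + THD1,6,3,0,MST,apparent
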