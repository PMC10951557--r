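trait,best_model,k,pseudo_R2,stars
leaf_area,Intercept only,         11,NA,
sla,min_seasonal_precip+max_drought_dur,         12,        100,**
asat,Intercept only,         11,NA,
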