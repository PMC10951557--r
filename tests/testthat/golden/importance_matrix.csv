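metric,group,leaf_area,sla,asat
mean_temp,Mean,0.07497719295,0.06472044823,0.0653444278
mean_precip,Mean,0.06352012412,0.05031417772,0.09771391542
temp_var,Variability,0.07332611645,0.1116154002,0.06184537147
precip_var,Variability,0.09011350175,0.130870671,0.2916690119
temp_range,Range,0.08146743337,0.06963538791,0.06462204466
precip_range,Range,0.1552901903,0.1629266547,0.08221580612
max_seasonal_precip,Seasonal precip.,0.06974759737,0.09763581891,0.08055649746
min_seasonal_precip,Seasonal precip.,0.0987263623,0.2820022858,0.06287584357
vpd,Aridity,0.09329102377,0.120216533,0.08886346529
max_drought_dur,Climate extremes,0.140890818,0.2799485088,0.09937952013
max_heatwave_dur,Climate extremes,0.082889419,0.05909905923,0.08496096033
max_dryspell_dur,Climate extremes,0.07005927317,0.05435992025,0.07119270816
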