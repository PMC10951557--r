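trait,moderator,k,slope,se,zval,p,significant,pseudo_R2,tau2,intercept,intercept_p,intercept_significant
leaf_area,mean_temp,         11,0.02092329809,0.03623229355,0.5774765008,0.5636176086,FALSE,          0,          0,0.001697077066,0.9723129445,FALSE
leaf_area,mean_precip,         11,0.0004477946015,0.1358656637,0.003295862909,0.9973702866,FALSE,          0,8.091192853e-05,0.02515796602,0.4123045068,FALSE
sla,mean_temp,         12,0.03178598435,0.040692618,0.7811240936,0.4347295125,FALSE,          0,0.004155578328,0.0639530352,0.2093687038,FALSE
sla,mean_precip,         12,-0.01800113774,0.1444366416,-0.1246299938,0.9008164819,FALSE,          0,0.005045089235,0.09734013758,0.006018559972,TRUE
asat,mean_temp,         11,-0.003182635062,0.03572337049,-0.0890911193,0.9290094951,FALSE,          0,0.001580324903,0.01137135979,0.7894363894,FALSE
asat,mean_precip,         11,0.1107392839,0.1182974717,0.9361086283,0.349217261,FALSE,          0,0.000951270302,-0.003034093524,0.9157647786,FALSE
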