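trait,moderator,k,slope,se,zval,p,significant,pseudo_R2,tau2,intercept,intercept_p,intercept_significant
econ_PC1,mean_temp,         12,0.03461352564,0.3801997665,0.09104036531,0.9274605173,FALSE,          0,          0,-0.03493671121,0.9420021199,FALSE
econ_PC1,mean_precip,         12,-0.1472961852,1.392345277,-0.1057899845,0.9157489834,FALSE,          0,          0,0.01173097442,0.9697396843,FALSE
econ_PC2,mean_temp,         12,0.03375633473,0.3801997665,0.088785785,0.929252155,FALSE,          0,          0,-0.03407151673,0.9434359763,FALSE
econ_PC2,mean_precip,         12,0.1398033309,1.392345277,0.1004085217,0.9200200046,FALSE,          0,          0,-0.01113422792,0.9712783225,FALSE
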