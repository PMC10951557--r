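species,mean_temp,mean_precip,temp_var,precip_var,temp_range,precip_range,max_seasonal_precip,min_seasonal_precip,vpd,max_drought_dur,max_heatwave_dur,max_dryspell_dur
sp01,1.514751837,0.05685251091,0.01816252932,0.1652147901,6.991641569,0.2393897721,0.1447752312,0.2545644993,0.09059346106,0.2787134025,-0.8979415932,-0.2231435513
sp02,-0.02036948387,0.1457578693,0.04493265227,-0.1445823251,4.698484688,0.4063714124,0.4062738708,0.2215668337,0.03220114793,0.08223809824,0.6931471806,0.9444616088
sp03,1.660813098,-0.0196494378,0.004503972302,0.01624340268,0.2483981157,-0.01457691296,0.2695715477,0.3022081089,0.1103159401,-0.06899287149,-0.2231435513,0.1053605157
sp04,2.294738297,-0.1131688687,-0.008462092594,-0.1491020824,3.160773192,0.07887343273,-0.1512019402,-0.3547536001,0.1846276385,0.3327057538,-0.5465437064,-0.2006706955
sp05,0.07665500553,-0.1681646776,0.001644965485,0.2003768335,1.552442719,-0.05005695372,0.09644248573,0.05535167732,-0.03528757147,0.4289956055,-0.2623642645,-0.3184537311
sp06,1.419269599,0.1359388189,-0.03815668808,0.1228868374,0.1983933244,-0.2140258002,-0.06163236449,0.05192142144,0.1069535585,0.3053816496,-0.4700036292,-0.1053605157
sp07,0.5685946735,-0.07016059286,0.03066173528,-0.01991925398,2.378033845,-0.1004528327,-0.1518071761,0.232086212,0.07543991146,          0,-0.1670540847,0.2231435513
sp08,0.5805799024,0.07973073044,-2.249649851e-05,-0.2008870722,0.1262570992,-0.1894530403,-0.4221645079,-0.1656917195,0.04182515437,0.08004270767,0.06899287149,0.4855078158
sp09,0.4091369785,0.2857425797,0.02261095284,-0.0356448271,1.512465582,0.3165466124,0.2578264002,0.3229792963,0.05674499457,-0.1892419996,0.4519851237,0.2623642645
sp10,1.808694897,0.5630475293,0.02091646823,0.1402597513,2.137116393,0.08538053454,0.3049003871,0.082375694,0.09586512896,0.4855078158,          0,0.1177830357
sp11,0.1626409818,-0.1889447072,0.003474930686,-0.01223400559,0.3042770199,0.1218278738,0.01634284901,0.01096915376,-0.06992205577,1.080912712,0.2231435513,0.4519851237
sp12,1.636537896,0.2487231934,0.03550472492,0.2904439589,4.728960305,0.002546577279,0.1935245737, 0.21186006,0.1507231652,0.06899287149,0.2411620568,0.2513144283
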