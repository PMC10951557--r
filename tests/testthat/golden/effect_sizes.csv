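species,trait,yi,vi,usable,reason
sp01,leaf_area,-0.07328034973,0.008234212675,TRUE,
sp01,sla,-0.00595732667,0.007814880469,TRUE,
sp01,asat,-0.01364770558,0.006335427322,TRUE,
sp01,leaf_n,0.05855769884,0.00592329182,TRUE,
sp02,leaf_area,-0.03002289896,0.007908530909,TRUE,
sp02,sla,0.1225925217,0.006326573067,TRUE,
sp02,asat,-0.02143815957,0.006161848228,TRUE,
sp02,leaf_n,-0.04320331019,0.01452421103,TRUE,
sp03,leaf_area,0.1215203366,0.005706403646,TRUE,
sp03,sla,0.2011726981,0.01674658251,TRUE,
sp03,leaf_n,-0.004605507949,0.005307140803,TRUE,
sp04,leaf_area,-0.04916649264,0.01044827289,TRUE,
sp04,sla,0.2284890881,0.008573698937,TRUE,
sp04,asat,-0.1390209141,0.008920699512,TRUE,
sp04,leaf_n,0.0767167377,0.005550686285,TRUE,
sp05,leaf_area,-0.006324383849,0.008767763383,TRUE,
sp05,sla, 0.13139179,0.007282610236,TRUE,
sp05,asat,0.08811132767,0.005818004867,TRUE,
sp05,leaf_n,0.02811832047,0.003887334008,TRUE,
sp06,leaf_area,0.03672564663,0.005230004782,TRUE,
sp06,sla,0.2092317967,0.01300225907,TRUE,
sp06,asat,-0.02910255775,0.009254279708,TRUE,
sp06,leaf_n,-0.02936623551,0.009068412339,TRUE,
sp07,sla,0.1075928981,0.0107062952,TRUE,
sp07,asat,-0.1241664814,0.006450637549,TRUE,
sp07,leaf_n,0.03365461104,0.00456353483,TRUE,
sp08,leaf_area,0.04273472944,0.009264864787,TRUE,
sp08,sla,0.2429718113,0.007631679189,TRUE,
sp08,asat,0.06530974588,0.006788690704,TRUE,
sp08,leaf_n,0.1442455796,0.004401476587,TRUE,
sp09,leaf_area,0.01108386923,0.009170901567,TRUE,
sp09,sla,-0.03665824656,0.01186290617,TRUE,
sp09,asat,-0.04276757893,0.004733480596,TRUE,
sp09,leaf_n,-0.01651476433,0.004875435018,TRUE,
sp10,leaf_area,-0.05648353973,0.008424234684,TRUE,
sp10,sla,0.09871242558,0.004161391921,TRUE,
sp10,asat,0.08841404764,0.005809401178,TRUE,
sp10,leaf_n,0.1904440602,0.007131294184,TRUE,
sp11,leaf_area,-0.01012418442,0.01395726491,TRUE,
sp11,sla,-0.05686291927,0.004499170329,TRUE,
sp11,asat,0.0469926074,0.007585031225,TRUE,
sp11,leaf_n,0.0254189797,0.01143320972,TRUE,
sp12,leaf_area,0.1582153097,0.005871386129,TRUE,
sp12,sla,0.01077403128,0.006907896063,TRUE,
sp12,asat,0.1052739732,0.004410533157,TRUE,
sp12,leaf_n,0.1512512895,0.01288460108,TRUE,
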