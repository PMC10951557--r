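species,overall_change
sp01,0.008581920783
sp02,0.006982038244
sp03,0.1060291756
sp04,0.02925460478
sp05,0.06032426357
sp06,0.04687216251
sp07,0.00569367591
sp08,0.1238154665
sp09,0.02121418015
sp10,0.08027174843
sp11,0.001356120849
sp12,0.1063786509
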