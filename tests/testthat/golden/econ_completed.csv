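species,delta_sla,delta_asat,delta_n
sp01,-0.00595732667,-0.01364770558,0.05855769884
sp02,0.1225925217,-0.02143815957,-0.04320331019
sp03,0.2011726981,-0.05964961879,-0.004605507949
sp04,0.2284890881,-0.1390209141,0.0767167377
sp05, 0.13139179,0.08811132767,0.02811832047
sp06,0.2092317967,-0.02910255775,-0.02936623551
sp07,0.1075928981,-0.1241664814,0.03365461104
sp08,0.2429718113,0.06530974588,0.1442455796
sp09,-0.03665824656,-0.04276757893,-0.01651476433
sp10,0.09871242558,0.08841404764,0.1904440602
sp11,-0.05686291927,0.0469926074,0.0254189797
sp12,0.01077403128,0.1052739732,0.1512512895
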