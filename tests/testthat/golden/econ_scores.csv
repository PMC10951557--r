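species,PC1,PC2,vi
sp01,-0.09152807089,-0.05242412914,          1
sp02,0.04256940735,-0.06590522511,          1
sp03,0.1207334909,-0.02529734206,          1
sp04,0.165786432,-0.003257561545,          1
sp05,-0.01507882815,0.04915330838,          1
sp06,0.1181290105,-0.0207467831,          1
sp07,0.06299549161,-0.07991793117,          1
sp08,0.06927587321,0.1662450167,          1
sp09,-0.08977787044,-0.1340465077,          1
sp10,-0.07479056728,0.1437170986,          1
sp11,-0.1574357094,-0.06363667558,          1
sp12,-0.1508786595,0.08611673167,          1
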