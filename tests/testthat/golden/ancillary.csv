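covariate,n,adj_R2,p
growth_form,         12,0.2157135358,0.1914114555
lifespan,          3,0.02111022966,0.493279906
co2_lnrr,         12,-0.09116608202,0.7818077298
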