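retained_components: 2
rule: mean
explained_pct: 52.27655066,36.29411117,11.42933816
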