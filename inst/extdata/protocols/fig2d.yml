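name: fig2d
model: meiosis
genotype: pat1_114_30C
t_starve: .na.real
t_readd: .na.real
horizon: 600.0
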