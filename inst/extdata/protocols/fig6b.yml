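name: fig6b
model: integrated
genotype: wild_type
t_starve: 135.0
t_readd: .na.real
horizon: 700.0
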