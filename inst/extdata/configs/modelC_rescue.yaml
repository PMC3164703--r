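# Transient exogenous Mitfa in the sox10 mutant: a plateau of 10x M* for
# 10 h drives the network into the differentiated attractor.
variant: C
rescue: {amplitude: 0.1, t_on: 30, t_off: 40, decay_rate: 1}
integration: {t0: 0, t1: 96, dt: 0.01}
seed: 1
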