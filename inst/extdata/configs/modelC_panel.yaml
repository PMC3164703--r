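# Four-genotype panel (WT, mitfa, sox10, double) under Model C.
variant: C
integration: {t0: 0, t1: 96, dt: 0.01}
seed: 1
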