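# Minimal feed-forward repression motif, wild type: both sox10 and mitfa
# are predicted to stay on (the behaviour that leads to this model's
# rejection).
variant: A
integration: {t0: 0, t1: 96, dt: 0.01}
seed: 1
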