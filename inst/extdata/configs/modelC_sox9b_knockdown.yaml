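# Sox9b (Factor Z) knockdown in the sox10 mutant background.
variant: C
knockdown: {factorZ_scale: 0.3, mitfa_activity: 1}
integration: {t0: 0, t1: 96, dt: 0.01}
seed: 1
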