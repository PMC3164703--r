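# Trichostatin-A-style Hdac blockade during 24-48 hpf.
variant: C
hdac: {window_start: 24, window_end: 48}
integration: {t0: 0, t1: 96, dt: 0.01}
seed: 1
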