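# Model B (Hdac on the Mitfa->sox10 term only, ungated Factor Y loop):
# sox10 stays above detection in the wild type because constant Factor A
# input is not Hdac-gated.
variant: B
integration: {t0: 0, t1: 96, dt: 0.01}
seed: 1
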