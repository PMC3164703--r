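# Synthetic per-embryo scoring of sox10-positive melanocytes, 20 cells from
# each of 5 embryos per time point over the 30-51 hpf window.
variant: C
synth: {species: S, n_fish: 5, cells_per_fish: 20, cv: 0.3}
integration: {t0: 0, t1: 96, dt: 0.01}
seed: 1
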