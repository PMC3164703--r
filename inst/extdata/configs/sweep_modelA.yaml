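# Pairwise robustness sweep of the minimal motif (first default pair:
# alpha x gamma, two orders of magnitude).
variant: A
sweep: {param_x: alpha, param_y: gamma, fold_range: 100, n_grid: 21}
integration: {t0: 0, t1: 96, dt: 0.05}
seed: 1
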