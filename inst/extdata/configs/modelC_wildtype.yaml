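# Reference Model C wild-type time course (the calibrated default set).
variant: C
integration: {t0: 0, t1: 96, dt: 0.01}
thresholds: {theta_det: 0.01, r_min: 5, t_late: 60}
seed: 1
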