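# melGRN

Dynamical models of the zebrafish melanocyte gene regulatory network.

## What this is for

When a neural crest cell becomes a melanocyte, the specifier *sox10* turns
on the master regulator *mitfa* and is then itself switched off, while
*mitfa* and the melanogenic differentiation genes (*dct*, *tyr*, *silva*)
stay on. Two regulatory facts make that switch nontrivial: Sox10 represses
the very differentiation genes whose master regulator it induces (a
feed-forward repression motif that delays differentiation until Sox10 is
cleared), and transient Mitfa alone can lock in stable differentiation even
without Sox10, implying a thresholded, Mitfa-autonomous positive feedback.

melGRN implements this circuit as a family of ODE models for anyone who
wants to simulate, perturb, and stress-test the network logic: three nested
variants (Model A, the minimal motif; Model B, adding Hdac repression and a
Sox10-independent feedback factor Y; Model C, adding Hdac gating of the
upstream input, hard thresholds on the Y loop, and a transient Factor B/Z
route into the differentiation genes), plus the in-silico experiments that
discriminate among them.

The regulatory logic is quasi-equilibrium Hill occupancy,
f(x; k) = kx/(1 + kx) for activation and g(x; k) = 1/(1 + kx) for
repression. Model C's core, in the field's notation:

    S' = c_S · min(1, f(A; α) g(H; φ) + f(M; σ) g(H; ξ)) · g(M; β) − d_S S
    M' = c_M · min(1, f(S; γ) + f(Y; δ_YM) Θ(Y − Y*)) − d_M M
    H' = c_H f(M; θ) − d_H H
    Y' = c_Y f(M; δ_MY) Θ(M − M*) − d_Y Y
    Z' = c_Z f(B; κ) − d_Z Z
    D' = c_D · min(1, f(M; μ_D) + w_Z f(Z; ζ)) · g(S; ρ) − d_D D
    T' = c_T f(M; μ_T) − d_T T

with S = sox10, M = mitfa, H = Hdac activity, Y/Z = hypothesised factors,
D = dct-class readout, T = tyrp1b, A/B exogenous inputs, and Θ a hard
threshold gate (M* = Y* = 0.01 nM). Genotypes are activity masks: a mutant
still transcribes, its product just stops acting.

## Worked example

```r
library(melGRN)
p  <- grn_params()                                  # calibrated reference set
wt <- grn_integrate("C", p, t0 = 0, t1 = 96, dt = 0.01)
behaviour_flags(wt)
```

```
<grn_behaviour>
  mitfa maintained:      TRUE
  sox10 transient peak:  TRUE (ratio 419 at 17.7 hpf)
  sox10 off at end:      TRUE
```

The wild-type run shows the defining behaviour: *mitfa* stays above the
0.01 nM detection threshold for the whole second half of the run, *sox10*
peaks at 17.7 hpf at 419 times its final level, and ends undetectable —
specification followed by clean shutdown.

The *sox10* mutant is bistable:

```r
ss <- find_steady_states("C", p, genotype_sox10_null())
for (s in ss) print(s)
```

```
<grn_steady_state> Model C, sox10 | stable | residual 0
   S=0.8333 M=0 H=0 Y=0 Z=0 D=0 T=0
  gate regime: thM=0 thY=0
<grn_steady_state> Model C, sox10 | stable | residual 1.1e-16
   S=0.001043 M=0.915 H=28.35 Y=1.077 Z=0 D=0.8206 T=0.733
  gate regime: thM=1 thY=1
```

Two attractors: the undifferentiated state (Mitfa off, persistent *sox10*
transcript — the mutant keeps expressing what it cannot use) and the
differentiated state (Mitfa high, *sox10* shut down). A transient exogenous
Mitfa pulse above the M* gate flips the first into the second
(`run_rescue()`), a pulse below it never does.

The synthetic observation layer scores simulated in situ detectability the
way an experimenter would — 20 pigmented cells in each of 5 embryos per
time point:

```r
score_cells(wt, "S", seed = 1)
```

```
  time_hpf n_positive n_total percent_positive
1       30        100     100              100
2       33        100     100              100
3       36        100     100              100
4       39        100     100              100
5       42         83     100               83
6       45         26     100               26
7       48          1     100                1
8       51          0     100                0
```

— every melanocyte *sox10*-positive at 30 hpf, none by 51 hpf.

Other entry points: `run_panel()` (WT/*mitfa*/*sox10*/double-mutant panel
with per-contract pass/fail), `run_hdac_inhibition()` (Trichostatin-style
windows), `run_overexpression()` (blastula RNA injection logic),
`run_sox9b_knockdown()`, `sweep_pairwise()`/`acceptable_fraction()`
(two-orders-of-magnitude robustness grids that reject Models A and B and
accept Model C), and `run_command()` — also available as a shell tool:

```sh
Rscript inst/cli/melgrn.R simulate \
  --config inst/extdata/configs/modelC_wildtype.yaml --out out/
```

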