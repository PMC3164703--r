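---
title: "Modelling the melanocyte gene regulatory network: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling the melanocyte gene regulatory network: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", fig.width = 6)
library(melGRN)
```

## The biological problem

During zebrafish development, neural crest cells that adopt the melanocyte
fate first express the SoxE transcription factor *sox10*, which activates
the master regulator *mitfa* (the zebrafish Mitf orthologue). As the cells
differentiate, *sox10* is switched off while *mitfa* and the melanogenic
differentiation genes (*dct*, *tyr*, *silva*; *tyrp1b* behaves differently)
stay on. Two observations make this switch mechanistically interesting:
Sox10, although required to initiate the program, represses the
differentiation genes while it is present (a feed-forward repression
motif that delays differentiation), and transient Mitfa alone can lock in
stable differentiation even in *sox10* mutants, pointing to a
Mitfa-autonomous positive feedback with a threshold.

melGRN implements this circuit as a family of deterministic ODE models and
reproduces, in silico, the experiments that discriminate among them:
mutant panels, transient-Mitfa rescue of the *sox10* mutant, RNA
overexpression at blastula stages, chemical Hdac inhibition, and Sox9b
knockdown.

## The model family

State species (concentrations in nM): `S` (*sox10* product), `M` (*mitfa*
product), `H` (Mitfa-recruited Hdac activity), `Y` (Factor Y, the
Sox10-independent positive feedback on *mitfa*, possibly Mitfa itself),
`Z` (Factor Z, the Sox10/Mitfa-independent weak activator of
differentiation genes; Sox9b contributes to it), `D` (dct-class
differentiation gene product) and `T` (*tyrp1b* product). Factor A (the
composite of *sox10* enhancer inputs: Wnt/Lef-Tcf, FoxD3, Pax, AP2, ...)
and Factor B (the transient inducer of Z) are exogenous inputs, not state
variables.

Regulation is one-step: transcription-factor binding is assumed fast
relative to synthesis and degradation (quasi-equilibrium), which gives
first-order Hill occupancies

$$f(x; k) = \frac{kx}{1 + kx}, \qquad g(x; k) = \frac{1}{1 + kx},$$

for activation and repression, with each affinity $k$ a binding/unbinding
ratio in 1/nM. The full Model C right-hand side is

$$
\begin{aligned}
S' &= c_S\,\min\!\bigl(1,\; f(A;\alpha)\,g(H;\varphi) + f(M;\sigma)\,g(H;\xi)\bigr)\,g(M;\beta) - d_S S\\
M' &= c_M\,\min\!\bigl(1,\; f(S;\gamma) + f(Y;\delta_{YM})\,\Theta(Y - Y^*)\bigr) - d_M M\\
H' &= c_H\, f(M;\theta) - d_H H\\
Y' &= c_Y\, f(M;\delta_{MY})\,\Theta(M - M^*) - d_Y Y\\
Z' &= c_Z\, f(B;\kappa) - d_Z Z\\
D' &= c_D\,\min\!\bigl(1,\; f(M;\mu_D) + w_Z f(Z;\zeta)\bigr)\,g(S;\rho) - d_D D\\
T' &= c_T\, f(M;\mu_T) - d_T T
\end{aligned}
$$

where $\Theta$ is a Heaviside gate (inclusive at the boundary) with
thresholds $M^* = Y^* = 0.01$ nM. Model B is Model C with $\varphi = 0$, no
gates, and no B/Z route; Model A further removes H and Y, leaving the
minimal motif $S' = c_S f(A;\alpha)g(M;\beta) - d_S S$,
$M' = c_M f(S;\gamma) - d_M M$. `variant_params()` performs exactly these
reductions, so the three right-hand sides nest to machine precision — a
property the test suite asserts on random states.

Design choices where the architecture was genuinely open:

* **Composition of co-activators.** Multiple activators of one promoter add
  and are capped at 1, so $c_g$ remains the true maximal rate. A purely
  multiplicative OR-gate was the alternative; the additive-capped form keeps
  each input individually sufficient, which the rescue and overexpression
  phenotypes require.
* **Hdac placement.** H multiplies each *sox10* activation term it gates
  ($\xi$ on the Mitfa term, $\varphi$ on the Factor A term). Model B lacks
  $\varphi$, and that single missing arrow is why it cannot shut *sox10*
  down under constant Factor A — the comparison the sweep module quantifies.
* **Hard gates.** The threshold response of the Factor Y loop is a Heaviside
  step; `gate_soft()` (a steepness-20 Hill) is available for smooth-solver
  work. The gates, not Hill exponents, provide ultrasensitivity: the
  one-step binding derivation fixes all Hill coefficients at 1.
* **Mutants as activity masking.** A null allele scales the *regulatory
  influence* of a product, never its synthesis: mutant transcripts continue
  to be produced (as observed for *sox10* and *mitfa* in the corresponding
  mutants), they simply do nothing downstream. Hdac inhibition zeroes H's
  repressive contribution inside treatment windows without touching H
  itself.

## The reference parameter set

No quantitative parameter measurements exist for this network; the
reference set shipped as the `grn_params()` defaults was calibrated once
against the qualitative behaviour the biology fixes, then frozen:

| quantity | value | rationale |
|---|---|---|
| $d_g$ (most species) | 0.2 /hr | hours-scale dynamics across 24–72 hpf |
| $c_g$ (gene products) | 0.2 nM/hr | expression scale $c/d = 1$ nM |
| $c_H, d_H$ | 8, 0.1 | H is a recruited activity, scale free; large amplitude with slow accumulation gives deep late repression of *sox10* without instant shutdown |
| $c_Y, d_Y$ | 1, 0.2 | the Factor Y relay needs loop gain > 1 ($c_Y \delta_{MY} \delta_{YM} c_M / (d_Y d_M) \approx 30$) |
| $\alpha, \beta, \sigma, \kappa, \zeta, \mu_D, \rho$ | 5 | mid-range affinities, half-saturation at 0.2 nM |
| $\gamma$ | 0.04 | weak Sox10→Mitfa activation: *mitfa* idles just above $M^*$ until the Factor Y loop ignites (~18–20 hpf), which is what delays *sox10* shutdown into the 30–50 hpf window |
| $\delta_{MY}, \delta_{YM}$ | 0.3, 10 | asymmetric relay: slow arming, strong closure |
| $\theta$ | 0.6 | Hdac responds weakly to idling Mitfa, strongly after ignition |
| $\xi, \varphi$ | 10 | with $H \approx 28$ at steady state, residual *sox10* synthesis is ~0.4% of maximal |
| $\mu_T$ | 3 | *tyrp1b* integrates Mitfa with a lag, giving the early/late injection distinction |
| $w_Z$ | 0.1 | Factor Z is a weak activator |
| $M^*, Y^*$ | 0.01 nM | feedback gate thresholds |
| Factor A | constant 1 nM from 12 hpf | *sox10*-inducing signals persist near the neural tube |
| Factor B | 1 nM on 12–30 hpf, then decay 0.2/hr | transient by construction; constant Z cannot produce the transient mutant *dct* signal |

The calibration logic is worth recording because it is forced, not
arbitrary: with Hill-1 kinetics every repressor crosses its half-effect
point early in its rise, so once Mitfa appears, *sox10* synthesis collapses
within a couple of hours. The observed timeline (melanocytes ~100%
*sox10*-positive at 30 hpf, none by ~50 hpf, with *mitfa* maintained) is
therefore only reachable if Mitfa itself stays low for several hours. The
reference set achieves this with a two-stage relay: Sox10 drives only an
idling level of Mitfa (just above $M^*$, opening the Y gate), Factor Y
accumulates toward a plateau a few-fold above $Y^*$ and crosses it after
~4–5 h, and only then does the strong $\delta_{YM}$ limb ignite full
*mitfa* expression, Hdac recruitment, and *sox10* shutdown. The same
threshold architecture makes the *sox10*-mutant off state genuinely stable
(bistability), which the ungated Model B cannot do.

One consequence of the gates worth knowing: besides the differentiated
attractor, wild-type Model C has a consistent low-Mitfa fixed point in the
all-gates-closed regime ($S \approx 0.25$, $M \approx 0.008$ nM). The
wild-type trajectory from rest passes it because Factor Y crosses $Y^*$
before decaying *sox10* can drag idling Mitfa below $M^*$; perturbations
that slow the relay (e.g. much weaker $\delta_{MY}$) would strand the
network there. This is a real feature of threshold positive feedback, not a
numerical artifact.

```{r wildtype, fig.alt = "Wild-type Model C time course"}
p <- grn_params()
wt <- grn_integrate("C", p, t0 = 0, t1 = 96, dt = 0.01)
plot(wt, species = c("S", "M", "D"))
behaviour_flags(wt)
```

## Numerics

* **Integration** is explicit Euler at `dt = 0.01` hr over 0–96 hpf, the
  scheme the models were designed around; the gates make the right-hand
  side discontinuous, which fixed-step Euler handles transparently. A step
  changing any species by more than 50% of its $c_g/d_g$ bound aborts with
  an error naming the species; negative undershoots (possible only with
  exogenous forcing) are clipped to zero and counted. The suite checks the
  default step against an adaptive multistep reference (deSolve's `lsoda`
  at `rtol = 1e-8`): the maximal discrepancy on the reference run is ~0.2%
  of each species' range, an order below the 2% requirement, and a
  decoupled species reproduces its closed-form saturation curve to O(dt).
* **Steady states** are found by gate-regime enumeration: within a regime
  the system is smooth and, given the inputs, triangular apart from the
  S–M pair, so every fixed point solves a scalar equation in M. That
  equation is bracketed on a 200-point log grid per regime (the
  deterministic multi-start), solved by `uniroot` to $10^{-13}$, checked
  for regime self-consistency (inclusive boundaries), verified against the
  full right-hand side (residual $\le 10^{-10}$ nM/hr), and deduplicated at
  $10^{-6}$ nM. Stability comes from the eigenvalues of a central
  finite-difference Jacobian with the gates frozen at the point's regime,
  restricted to the species active in the variant; points within $10^{-6}$
  nM of a gate boundary are reported boundary-degenerate.
  `consistency_check()` closes the loop by integrating from ±1%
  perturbations back to the point.
* **Sweeps** vary two affinities on a log grid spanning two orders of
  magnitude around the reference base (21×21 by default; the tests use
  11×11) and re-integrate the wild type at every point, recording steady
  Mitfa and Sox10 (end-of-run values; all timescales are ≤10 hr, so 96 hpf
  is fully relaxed) and the Sox10 maximum along the trajectory. A point is
  acceptable when $M_{ss} \ge \theta_{det}$, $S_{ss} < \theta_{det}$ and
  $S_{max}/\max(S_{ss}, 10^{-6}) \ge r_{min}$.

## Detection thresholds

The mapping from simulated nM to "detectable by in situ hybridisation" is a
declared convention, not a measured value: `theta_det = 0.01` nM, the same
scale as the feedback thresholds, with `r_min = 5` quantifying an
"appreciable" peak-to-late ratio and `t_late = 60` hpf for the maintenance
criterion. The RNA overexpression scenario deliberately uses a different,
"robust expression" threshold (`theta_on = 0.35` nM, ~35% of saturation):
at 1% of saturation any nonzero input in a cascade with 5-hr timescales is
"on" within an hour, so `theta_det` cannot discriminate a 6-hpf from a
10.5-hpf assay point; strong whole-mount staining corresponds to
substantial, not threshold, expression. With that single convention the
injection logic comes out of the model unchanged: Mitfa alone switches
differentiation genes on early; Sox10 alone induces *mitfa* early and
*tyrp1b* only late; co-injection gives early *tyrp1b* but keeps the
dct-class off. These injection contracts encode a consistency argument —
the originating study did not simulate them — and are flagged as an
extension.

## The synthetic observation layer

Two readout generators make the observation contracts testable without any
external data:

* `score_cells()` emulates per-embryo scoring of detectable expression: 20
  pigmented cells from each of 5 embryos per time point, scored over
  30–51 hpf at 3-hr intervals. Each cell draws an independent lognormal
  multiplier with median 1 (so a cell exactly at threshold is positive with
  probability 1/2) and coefficient of variation 0.3, representing
  cell-to-cell variation in transcript level and stain; a cell is positive
  iff its multiplied level reaches `theta_det`. Counts are therefore
  binomial with trajectory-dependent success probabilities — a property the
  suite checks against binomial bounds.
* `qpcr_foldchange()` emulates normalized qPCR: replicates of
  $100 \cdot x_{geno}(t)/x_{WT}(t) \cdot e^{N(0, cv)}$, percent of wild
  type with multiplicative noise.

What the generator emulates is the *statistical shape* of the readouts
(sampling depth, per-cell detection, multiplicative noise). What it does
not emulate: embryo-to-embryo staging variation, spatial heterogeneity
along the body axis, probe-specific sensitivity, or mosaicism of injected
RNA. Passing the shape tests therefore shows the model produces the right
detectability time course under an idealised observer, not that it fits any
real staining series quantitatively.

## Problem sizes and determinism

The shipped tests and the acceptance script use the reference grid
(`dt = 0.01`, 0–96 hpf) for single runs, `dt = 0.02`–`0.05` for
multi-trajectory scenarios, 11×11 log grids for the sweeps, and 200 seeds
for the scoring envelope — sizes chosen so the whole analysis reruns in
about a minute on one core while leaving every qualitative margin wide.
All randomness (cell scoring, fold-change noise) flows through explicit
seeds; trajectories themselves are deterministic, and identical
configurations produce byte-identical exports (the config hash recorded in
every summary makes this checkable).

## Known limitations

* Concentrations are in nominal nM: the scale $c/d = 1$ nM is a choice, and
  only ratios to the declared thresholds carry meaning.
* The Hill-1/quasi-equilibrium reduction compresses transcription,
  translation and protein turnover into one step; mRNA/protein lags are
  absorbed into the effective degradation rates.
* Hard gates make the right-hand side discontinuous: fixed points exactly
  on a gate boundary are reported as boundary-degenerate rather than
  classified, and derivative-based bifurcation tooling would need
  `gate_soft()`.
* The model is single-cell and deterministic — no stochastic gene
  expression, no cell migration or division, no iridophore/other-fate
  branches, and no promoter-sequence level detail.
* Model B's rejection is base-point specific in one corner: on the
  (α, β) grid a ~2% sliver of extreme repression strengths technically
  meets the criteria, while on its own default (ξ, ·) sweeps it meets them
  nowhere. The discriminating comparisons are the default sweeps.
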