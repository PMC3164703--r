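Package: melGRN
Title: Dynamical Models of the Zebrafish Melanocyte Gene Regulatory Network
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Ordinary-differential-equation models of melanocyte
    specification and differentiation in the zebrafish neural crest, built
    from Hill-type transcriptional logic around sox10 and mitfa. Provides
    three nested model variants of increasing refinement (a minimal
    feed-forward repression motif; added Hdac repression and a
    Sox10-independent positive feedback on mitfa; threshold gating of that
    feedback plus a transient Factor B/Z input to the differentiation
    genes), wild-type and mutant time-course simulation by explicit Euler
    integration, behaviour-criteria classification, steady-state and
    bistability analysis by gate-regime enumeration, canonical in-silico
    experiments (mutant panels, transient-Mitfa rescue, RNA overexpression,
    Hdac inhibition, Sox9b knockdown), pairwise parameter-robustness sweeps,
    and a synthetic-observation layer emulating per-embryo cell scoring and
    qPCR-style fold-change readouts.
License: MIT + file LICENSE
Encoding: UTF-8
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    graphics,
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    deSolve,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
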