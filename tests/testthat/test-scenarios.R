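# The scenario suite runs on a coarser grid (dt = 0.05 hr); calibration of
# the reference set was verified at dt = 0.01 and the dynamics are smooth on
# the hours scale, so the qualitative contracts are grid-insensitive.

test_that("the Model C reference panel satisfies every mutant contract", {
  pan <- run_panel("C", ref_params(), dt = fast_dt)
  expect_true(all(pan$contracts))
  # metrics are pure functions of the trajectories: recompute and compare
  m <- pan$metrics
  for (i in seq_len(nrow(m))) {
    tr <- pan$trajectories[[m$genotype[i]]]
    expect_equal(m$duration_above_hr[i],
                 duration_above(tr, m$species[i], pan$theta_det))
    expect_equal(m$peak_nM[i], peak_level(tr, m$species[i]))
  }
})

test_that("Model B fails the wild-type sox10 shutdown contract", {
  pan <- run_panel("B", ref_params(), dt = fast_dt)
  expect_false(pan$contracts[["sox10_off_in_wt"]])
})

test_that("double mutant dct output is structurally identical to sox10 mutant", {
  pan <- run_panel("C", ref_params(), dt = fast_dt)
  expect_equal(trajectory_species(pan$trajectories$double, "D"),
               trajectory_species(pan$trajectories$sox10, "D"),
               tolerance = 1e-12)
})

test_that("rescue outcome is a threshold phenomenon in the pulse plateau", {
  p <- ref_params()
  # a plateau below M* can never open the Mitfa gate, whatever its duration
  lo <- run_rescue(p, pulse(0.5 * p$M_star, 30, 70, decay_rate = 1),
                   dt = fast_dt)
  expect_identical(lo$converged_to, "off")
  expect_lt(max(trajectory_species(lo$trajectory, "Y")), p$Y_star)
  # a 10x M* plateau held 10 h ignites the loop and locks differentiation
  hi <- run_rescue(p, pulse(10 * p$M_star, 30, 40, decay_rate = 1),
                   dt = fast_dt)
  expect_identical(hi$converged_to, "on")
  # zero pulse trivially stays off
  z <- run_rescue(p, pulse(0), dt = fast_dt)
  expect_identical(z$converged_to, "off")
  # monotonicity: a pointwise-dominating pulse cannot turn "on" into "off"
  hi2 <- run_rescue(p, pulse(20 * p$M_star, 30, 45, decay_rate = 1),
                    dt = fast_dt)
  expect_identical(hi2$converged_to, "on")
})

test_that("overexpression readouts reproduce the injection logic", {
  p <- ref_params()
  on_at <- function(res, sp, when) {
    res$readout[res$readout$species == sp, paste0("on_", when)]
  }
  # nothing injected, nothing on
  null <- run_overexpression(p, 0, 0, dt = fast_dt)
  expect_false(any(null$readout$on_early | null$readout$on_late))
  # mitfa alone drives differentiation genes early
  m_only <- run_overexpression(p, init_S = 0, init_M = 10, dt = fast_dt)
  expect_true(on_at(m_only, "D", "early"))
  expect_true(on_at(m_only, "T", "early"))
  # sox10 alone induces mitfa early; tyrp1b only late; dct-class never
  s_only <- run_overexpression(p, init_S = 10, init_M = 0, dt = fast_dt)
  expect_true(on_at(s_only, "M", "early"))
  expect_false(on_at(s_only, "T", "early"))
  expect_true(on_at(s_only, "T", "late"))
  expect_false(on_at(s_only, "D", "early"))
  expect_false(on_at(s_only, "D", "late"))
  # co-injection: tyrp1b escapes Sox10 repression, dct-class does not
  both <- run_overexpression(p, init_S = 10, init_M = 10, dt = fast_dt)
  expect_true(on_at(both, "T", "early"))
  expect_false(on_at(both, "D", "early"))
  expect_false(on_at(both, "D", "late"))
})

test_that("Hdac inhibition prolongs sox10 Mitfa-dependently and delays dct", {
  p <- ref_params()
  res <- run_hdac_inhibition(p, c(24, 48), dt = fast_dt)
  s <- res$summary
  expect_gt(s$wt_S_window_end_treated, s$theta_det)
  expect_lt(s$wt_S_window_end_control, s$theta_det)
  expect_lt(s$wt_D_peak_treated, s$wt_D_peak_control)
  # no Mitfa, no recruited Hdac: treatment cannot change the mutant
  expect_lt(s$mitfa_null_max_S_diff, 1e-6)
  # empty window: treated and control identical
  res0 <- run_hdac_inhibition(p, c(24, 24), dt = fast_dt)
  expect_identical(res0$wt_treated$values, res0$wt_control$values)
})

test_that("dct output falls monotonically with Factor Z knockdown", {
  p <- ref_params()
  scales <- c(0, 0.3, 0.6, 1)
  aucs <- vapply(scales, function(sc) {
    run_sox9b_knockdown(p, sc, dt = fast_dt)$auc_reduced
  }, numeric(1))
  expect_true(all(diff(aucs) > 0))
  kd <- run_sox9b_knockdown(p, 0.3, dt = fast_dt)
  expect_lt(kd$auc_reduced, kd$auc_full)
  # complete knockdown in the double mutant silences D entirely
  dn <- run_sox9b_knockdown(p, 0, mitfa_activity = 0, dt = fast_dt)
  expect_equal(max(trajectory_species(dn$reduced, "D")), 0)
})

test_that("dct output never decreases when genotype activities increase", {
  p <- ref_params()
  auc_for <- function(sox10, mitfa) {
    g <- genotype(sox10_activity = sox10, mitfa_activity = mitfa)
    auc_species(grn_integrate("C", p, g, dt = fast_dt), "D")
  }
  # increasing mitfa activity at fixed sox10
  expect_true(auc_for(0, 0.5) >= auc_for(0, 0))
  expect_true(auc_for(0, 1) >= auc_for(0, 0.5))
  expect_true(auc_for(1, 1) >= auc_for(1, 0.5))
})
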