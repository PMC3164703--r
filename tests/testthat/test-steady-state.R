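test_that("with no synthesis the origin is the unique stable fixed point", {
  p <- ref_params(c_S = 0, c_M = 0, c_H = 0, c_Y = 0, c_Z = 0, c_D = 0, c_T = 0)
  ss <- find_steady_states("C", p)
  expect_length(ss, 1)
  expect_equal(unname(ss[[1]]$concentrations), rep(0, 7))
  expect_true(ss[[1]]$stable)
  expect_lt(ss[[1]]$residual, 1e-10)
  expect_true(consistency_check(ss[[1]], p))
})

test_that("Model A keeps both sox10 and mitfa on at a unique stable point", {
  p <- ref_params()
  ss <- find_steady_states("A", p)
  expect_length(ss, 1)
  s <- ss[[1]]
  expect_true(s$stable)
  expect_gt(s$concentrations[["S"]], 0.01)
  expect_gt(s$concentrations[["M"]], 0.01)
  # cross-check against long integration
  tr <- grn_integrate("A", p, t1 = 400, dt = 0.05)
  expect_equal(unname(tr$values[nrow(tr$values), ]),
               unname(s$concentrations), tolerance = 1e-4)
})

test_that("Model C sox10 mutant is bistable: off state and differentiated state", {
  p <- ref_params()
  ss <- find_steady_states("C", p, genotype_sox10_null())
  stable <- Filter(function(s) isTRUE(s$stable), ss)
  expect_length(stable, 2)
  M_vals <- sort(vapply(stable, function(s) s$concentrations[["M"]], numeric(1)))
  expect_lt(M_vals[1], p$M_star)   # undifferentiated: Mitfa below the gate
  expect_gt(M_vals[2], 0.1)        # differentiated: high Mitfa
  # sox10 transcript persists in the off state (the mutant still expresses it)
  off <- stable[[which.min(vapply(stable, function(s) s$concentrations[["M"]],
                                  numeric(1)))]]
  expect_gt(off$concentrations[["S"]], 0.1)
  for (s in stable) {
    expect_lt(s$residual, 1e-10)
    expect_true(consistency_check(s, p))
  }
})

test_that("every reported fixed point satisfies the residual bound", {
  p <- ref_params()
  for (cfg in list(list("C", genotype_wt()),
                   list("C", genotype_mitfa_null()),
                   list("B", genotype_wt()),
                   list("A", genotype_sox10_null()))) {
    ss <- find_steady_states(cfg[[1]], p, cfg[[2]])
    for (s in ss) {
      expect_lt(s$residual, 1e-10)
      rhs_now <- grn_rhs(cfg[[1]], s$concentrations, t = 1e6, params = p,
                         geno = cfg[[2]])
      expect_lt(max(abs(rhs_now)), 1e-10)
    }
  }
})

test_that("stability classification matches analytic expectations", {
  # pure decay system: eigenvalues are -d_g, stable
  p0 <- ref_params(c_S = 0, c_M = 0, c_H = 0, c_Y = 0, c_Z = 0, c_D = 0, c_T = 0)
  ss0 <- find_steady_states("C", p0)[[1]]
  expect_true(classify_stability(ss0, p0))

  # Model B sox10-null origin: ungated Factor Y feedback makes the off state
  # unstable when the loop gain exceeds the degradation product
  p <- ref_params()
  g <- genotype_sox10_null()
  origin <- structure(list(variant = "B", genotype = g,
                           concentrations = stats::setNames(rep(0, 7),
                             c("S", "M", "H", "Y", "Z", "D", "T")),
                           regime = c(thM = 1, thY = 1), residual = 0,
                           stable = NA),
                      class = "grn_steady_state")
  # loop gain c_M*delta_YM * c_Y*delta_MY = 2 * 0.3 > d_M*d_Y = 0.04
  expect_false(classify_stability(origin, p))
  # perturb-and-integrate confirms divergence from the origin
  tr <- grn_integrate("B", p, g, t0 = 0, t1 = 150, dt = 0.02,
                      init = c(0, 1e-4, 0, 0, 0, 0, 0))
  expect_gt(tr$values[nrow(tr$values), "M"], 0.5)
  # while the gated Model C origin is stable under the same perturbation
  trC <- grn_integrate("C", ref_params(pulse_A = pulse(0), pulse_B = pulse(0)),
                       g, t0 = 0, t1 = 150, dt = 0.02,
                       init = c(0, 1e-4, 0, 0, 0, 0, 0))
  expect_lt(trC$values[nrow(trC$values), "M"], 1e-6)
})

test_that("a mislabeled unstable point fails the integrator cross-check", {
  p <- ref_params()
  g <- genotype_sox10_null()
  origin <- structure(list(variant = "B", genotype = g,
                           concentrations = stats::setNames(
                             c(0.1489, rep(1e-3, 6)),
                             c("S", "M", "H", "Y", "Z", "D", "T")),
                           regime = c(thM = 1, thY = 1), residual = 0,
                           stable = TRUE),
                      class = "grn_steady_state")
  expect_false(consistency_check(origin, p))
})

test_that("fixed points near a gate boundary report undetermined stability", {
  p <- ref_params()
  ss <- find_steady_states("C", p, genotype_sox10_null())[[1]]
  ss$concentrations[["M"]] <- p$M_star + 1e-8
  ss$concentrations[["Y"]] <- p$Y_star
  expect_true(is.na(classify_stability(ss, p)))
})
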