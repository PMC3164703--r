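test_that("noise-free scoring is a sharp threshold on the trajectory", {
  tr <- grn_integrate("C", ref_params(), dt = fast_dt)
  cs <- score_cells(tr, "S", times = c(30, 51), cv = 0, seed = 1)
  S30 <- trajectory_at(tr, "S", 30)
  S51 <- trajectory_at(tr, "S", 51)
  expect_gt(S30, 0.01)
  expect_lt(S51, 0.01)
  expect_equal(cs$n_positive, c(100L, 0L))
  expect_equal(cs$n_total, c(100, 100))
})

test_that("at the threshold the lognormal noise splits cells evenly", {
  # median-1 multiplier: P(m * theta >= theta) = 1/2, so counts are
  # Binomial(n, 1/2); check the pooled rate over many seeds against
  # 99% binomial bounds
  tr <- grn_integrate("C", ref_params(), t1 = 48, dt = fast_dt)
  t_at <- 40
  theta <- trajectory_at(tr, "S", t_at)  # score exactly at the current level
  n_seeds <- 60
  counts <- vapply(seq_len(n_seeds), function(s) {
    score_cells(tr, "S", times = t_at, theta_det = theta, cv = 0.5,
                seed = s)$n_positive
  }, integer(1))
  n_tot <- 100 * n_seeds
  ci <- qbinom(c(0.005, 0.995), n_tot, 0.5) / n_tot
  expect_gt(sum(counts) / n_tot, ci[1])
  expect_lt(sum(counts) / n_tot, ci[2])
})

test_that("scoring is deterministic under a seed and count-bounded", {
  tr <- grn_integrate("C", ref_params(), dt = fast_dt)
  a <- score_cells(tr, "S", seed = 99)
  b <- score_cells(tr, "S", seed = 99)
  expect_identical(a$n_positive, b$n_positive)
  expect_true(all(a$n_positive >= 0 & a$n_positive <= a$n_total))
  c2 <- score_cells(tr, "S", seed = 100)
  expect_false(identical(a$n_positive, c2$n_positive))
})

test_that("fold-change replicates centre on the exact trajectory ratio", {
  pan <- run_panel("C", ref_params(), dt = fast_dt)
  # noise-free: replicates equal the exact percent-of-WT
  fc0 <- qpcr_foldchange(pan, "D", time = 30, n_reps = 2, cv = 0, seed = 1)
  x_wt <- trajectory_at(pan$trajectories$WT, "D", 30)
  for (g in unique(fc0$genotype)) {
    x_g <- trajectory_at(pan$trajectories[[g]], "D", 30)
    expect_equal(fc0$percent_of_wt[fc0$genotype == g],
                 rep(100 * x_g / x_wt, 2))
  }
  # WT against itself is exactly 100%
  expect_equal(fc0$percent_of_wt[fc0$genotype == "WT"], c(100, 100))
  # with noise, WT replicates centre on 100% (log-scale mean 0)
  fc <- qpcr_foldchange(pan, "D", time = 30, n_reps = 200, cv = 0.2, seed = 3)
  wt_reps <- fc$percent_of_wt[fc$genotype == "WT"]
  expect_equal(mean(log(wt_reps / 100)), 0, tolerance = 0.05)
  expect_true(all(fc$percent_of_wt > 0))
})

test_that("early dct derepression is stronger in sox10 than mitfa mutants", {
  pan <- run_panel("C", ref_params(), dt = fast_dt)
  fc <- qpcr_foldchange(pan, "D", time = 30, n_reps = 25, cv = 0.2, seed = 5)
  m_sox10 <- mean(fc$percent_of_wt[fc$genotype == "sox10"])
  m_mitfa <- mean(fc$percent_of_wt[fc$genotype == "mitfa"])
  expect_gt(m_sox10, m_mitfa)
})

test_that("fold change is undefined when the wild-type level vanishes", {
  pan <- run_panel("C", ref_params(), t1 = 12, dt = fast_dt)
  expect_error(qpcr_foldchange(pan, "D", time = 5), "undefined")
})

test_that("fixture bundles are reproducible, hashed, and round-trip", {
  d1 <- file.path(tempdir(), "fix1")
  d2 <- file.path(tempdir(), "fix2")
  make_fixture(7, d1, dt = 0.1)
  make_fixture(7, d2, dt = 0.1)
  for (f in c("cell_scoring.csv", "foldchange.csv", "manifest.json")) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  fx <- read_fixture(d1)
  expect_true(all(c("species", "time_hpf", "n_positive") %in% names(fx$cells)))
  expect_true(all(fx$cells$n_positive <= fx$cells$n_total))
  expect_equal(fx$manifest$seed, 7)
  # different parameters change the manifest hash
  d3 <- file.path(tempdir(), "fix3")
  make_fixture(7, d3, params = ref_params(alpha = 2), dt = 0.1)
  expect_false(identical(read_fixture(d3)$manifest$config_hash,
                         fx$manifest$config_hash))
  unlink(c(d1, d2, d3), recursive = TRUE)
})
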