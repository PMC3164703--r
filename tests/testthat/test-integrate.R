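test_that("zero synthesis from a zero state stays identically zero", {
  p <- ref_params(c_S = 0, c_M = 0, c_H = 0, c_Y = 0, c_Z = 0, c_D = 0, c_T = 0)
  tr <- grn_integrate("C", p, t1 = 24, dt = 0.1)
  expect_true(all(tr$values == 0))
  expect_equal(tr$clip_count, 0L)
})

test_that("a decoupled species follows the closed-form saturation curve", {
  # only the Factor A -> sox10 route active, constant input from t = 0:
  # S(t) = (r/d) (1 - exp(-d t)) with r = c_S * f(A; alpha)
  p <- ref_params(gamma = 0, sigma = 0, theta = 0, delta_MY = 0, delta_YM = 0,
                  kappa = 0, mu_D = 0, mu_T = 0,
                  pulse_A = pulse(1, t_on = 0, t_off = Inf),
                  pulse_B = pulse(0))
  dt <- 0.01
  tr <- grn_integrate("C", p, t1 = 40, dt = dt)
  r <- p$c_S * hill_act(1, p$alpha)
  expected <- (r / p$d_S) * (1 - exp(-p$d_S * tr$times))
  err <- max(abs(trajectory_species(tr, "S") - expected))
  # explicit Euler: global error O(dt)
  expect_lt(err, 5 * dt * r)
  # and halving dt roughly halves the error
  tr2 <- grn_integrate("C", p, t1 = 40, dt = dt / 2)
  expected2 <- (r / p$d_S) * (1 - exp(-p$d_S * tr2$times))
  err2 <- max(abs(trajectory_species(tr2, "S") - expected2))
  expect_lt(err2, 0.75 * err)
})

test_that("grid self-convergence: halving dt barely changes the solution", {
  p <- ref_params()
  tr1 <- grn_integrate("C", p, t1 = 60, dt = 0.02)
  tr2 <- grn_integrate("C", p, t1 = 60, dt = 0.01)
  shared <- tr2$values[seq(1, nrow(tr2$values), by = 2), ]
  scale <- apply(tr1$values, 2, max)
  scale[scale == 0] <- 1
  rel <- max(abs(tr1$values - shared) %*% diag(1 / scale))
  expect_lt(rel, 0.02)
})

test_that("identical configuration replays bit-identically", {
  p <- ref_params()
  tr1 <- grn_integrate("C", p, t1 = 30, dt = fast_dt)
  tr2 <- grn_integrate("C", p, t1 = 30, dt = fast_dt)
  expect_identical(tr1$values, tr2$values)
  expect_identical(tr1$times, tr2$times)
})

test_that("an unstable step size aborts naming the runaway species", {
  expect_error(grn_integrate("C", ref_params(), t1 = 96, dt = 5),
               "unstable for species S")
})

test_that("integration rejects degenerate grids and negative initial states", {
  p <- ref_params()
  expect_error(grn_integrate("C", p, dt = 0), "dt")
  expect_error(grn_integrate("C", p, t0 = 10, t1 = 5), "t1")
  expect_error(grn_integrate("C", p, init = c(-1, rep(0, 6))), "non-negative")
})

test_that("trajectories export to tidy long format and back", {
  tr <- grn_integrate("C", ref_params(), t1 = 24, dt = 0.1)
  df <- as.data.frame(tr)
  expect_named(df, c("time_hpf", "species", "concentration_nM",
                     "genotype", "variant"))
  expect_equal(nrow(df), length(tr$times) * 7)
  expect_equal(df$concentration_nM[df$species == "M"],
               unname(trajectory_species(tr, "M")))
  tmp <- tempfile(fileext = ".csv")
  write_trajectory_csv(tr, tmp)
  back <- read.csv(tmp)
  expect_equal(nrow(back), nrow(df))
  expect_equal(back$concentration_nM[back$species == "S"],
               df$concentration_nM[df$species == "S"], tolerance = 1e-12)
})

test_that("trajectory interpolation matches grid values and guards range", {
  tr <- grn_integrate("C", ref_params(), t1 = 24, dt = 0.1)
  expect_equal(trajectory_at(tr, "S", tr$times[51]),
               trajectory_species(tr, "S")[51])
  expect_error(trajectory_at(tr, "S", 30), "outside")
})
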