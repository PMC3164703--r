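test_that("extinction and single-species balance points are fixed points", {
  p <- ref_params(pulse_A = pulse(0), pulse_B = pulse(0))
  d <- grn_rhs("A", rep(0, 7), t = 20, params = p)
  expect_equal(unname(d), rep(0, 7))

  # one-species balance: S at synthesis/degradation equilibrium with M fixed
  p2 <- ref_params()
  M_fix <- 0.3
  A_t <- pulse_value(50, p2$pulse_A)
  S_bal <- p2$c_S * hill_act(A_t, p2$alpha) * hill_rep(M_fix, p2$beta) / p2$d_S
  st <- c(S = S_bal, M = M_fix, H = 0, Y = 0, Z = 0, D = 0, T = 0)
  d2 <- grn_rhs("A", st, t = 50, params = p2)
  expect_equal(unname(d2[["S"]]), 0, tolerance = 1e-12)
})

test_that("mitfa-null reduces Hdac and Factor Y dynamics to pure decay", {
  p <- ref_params()
  g <- genotype_mitfa_null()
  set.seed(7)
  for (i in 1:25) {
    st <- random_state(scale = 2)
    d <- grn_rhs("C", st, t = runif(1, 0, 96), params = p, geno = g)
    expect_equal(unname(d[["H"]]), -p$d_H * st[["H"]], tolerance = 1e-12)
    expect_equal(unname(d[["Y"]]), -p$d_Y * st[["Y"]], tolerance = 1e-12)
  }
})

test_that("sox10-null derivatives are independent of rho and gamma", {
  g <- genotype_sox10_null()
  set.seed(11)
  for (i in 1:25) {
    st <- random_state(scale = 2)
    t <- runif(1, 0, 96)
    d1 <- grn_rhs("C", st, t, ref_params(rho = 0.3, gamma = 0.3), geno = g)
    d2 <- grn_rhs("C", st, t, ref_params(rho = 9, gamma = 9), geno = g)
    expect_equal(d1, d2, tolerance = 1e-12)
  }
})

test_that("model variants nest exactly: C reduces to B reduces to A", {
  set.seed(13)
  for (i in 1:40) {
    p <- random_params()
    st <- random_state(scale = 3)
    t <- runif(1, 0, 96)
    pB <- melGRN:::variant_params(p, "B")$params
    pA <- melGRN:::variant_params(p, "A")$params
    # A equals B under A's reductions for arbitrary states
    expect_equal(grn_rhs("B", st, t, pA), grn_rhs("A", st, t, p),
                 tolerance = 0)
    # B equals C under B's reductions; C keeps its gates, which agree with
    # B's ungated form whenever the state is above both thresholds
    st_hi <- st + 0.05
    expect_equal(grn_rhs("C", st_hi, t, pB), grn_rhs("B", st_hi, t, p),
                 tolerance = 0)
  }
})

test_that("the non-negative orthant is forward-invariant", {
  set.seed(17)
  for (i in 1:60) {
    p <- random_params()
    st <- random_state(scale = 2)
    # zero out a random subset of species
    idx <- sample(7, sample(1:7, 1))
    st[idx] <- 0
    for (v in c("A", "B", "C")) {
      d <- grn_rhs(v, st, t = runif(1, 0, 96), params = p)
      expect_true(all(d[idx] >= 0),
                  info = sprintf("variant %s draw %d", v, i))
    }
  }
})

test_that("synthesis never exceeds c_g so species are bounded by c_g/d_g", {
  set.seed(19)
  cg <- function(p) unlist(p[paste0("c_", c("S","M","H","Y","Z","D","T"))],
                           use.names = FALSE)
  dg <- function(p) unlist(p[paste0("d_", c("S","M","H","Y","Z","D","T"))],
                           use.names = FALSE)
  for (i in 1:40) {
    p <- random_params()
    st <- random_state(scale = 5)
    d <- grn_rhs("C", st, t = runif(1, 0, 96), params = p)
    # derivative plus degradation = synthesis term, must be within [0, c_g]
    synth <- unname(d) + dg(p) * unname(st)
    expect_true(all(synth <= cg(p) + 1e-12))
    expect_true(all(synth >= -1e-12))
  }
})

test_that("rhs rejects bad states and unknown variants", {
  p <- ref_params()
  expect_error(grn_rhs("Q", rep(0, 7), 0, p))
  expect_error(grn_rhs("C", c(NA, rep(0, 6)), 0, p), "NaN")
  expect_error(grn_rhs("C", c(-1, rep(0, 6)), 0, p), "non-negative")
  expect_error(grn_rhs("C", rep(0, 5), 0, p), "length")
})
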