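# Shared fixtures for the suite: the frozen reference set, a cheap grid for
# slow scenarios, and random-state generators used by property tests.

ref_params <- function(...) grn_params(...)

# Coarser grid for tests that only need qualitative structure.
fast_dt <- 0.05

random_state <- function(scale = 1) {
  st <- runif(7, 0, scale)
  names(st) <- c("S", "M", "H", "Y", "Z", "D", "T")
  st
}

# Random parameter draw spanning the plausible ranges: rates around the
# reference scales, affinities log-uniform in [0.1, 10].
random_params <- function() {
  aff <- function() exp(runif(1, log(0.1), log(10)))
  grn_params(
    c_S = runif(1, 0.05, 0.5), c_M = runif(1, 0.05, 0.5),
    c_H = runif(1, 0.05, 8), c_Y = runif(1, 0.05, 2),
    c_Z = runif(1, 0.05, 0.5), c_D = runif(1, 0.05, 0.5),
    c_T = runif(1, 0.05, 0.5),
    d_S = runif(1, 0.05, 0.5), d_M = runif(1, 0.05, 0.5),
    d_H = runif(1, 0.02, 0.5), d_Y = runif(1, 0.02, 0.5),
    d_Z = runif(1, 0.05, 0.5), d_D = runif(1, 0.05, 0.5),
    d_T = runif(1, 0.05, 0.5),
    alpha = aff(), beta = aff(), gamma = aff(), sigma = aff(),
    delta_MY = aff(), delta_YM = aff(), theta = aff(), xi = aff(),
    phi = aff(), kappa = aff(), zeta = aff(), w_Z = runif(1, 0.01, 1),
    mu_D = aff(), mu_T = aff(), rho = aff()
  )
}

# deSolve cross-check: integrate the same rhs with an adaptive higher-order
# method and return the solution at the requested times.
desolve_reference <- function(variant, params, geno = genotype_wt(),
                              times, init = rep(0, 7), method = "lsoda") {
  rhs <- melGRN:::make_rhs(variant, params, geno)
  out <- deSolve::ode(y = init, times = times,
                      func = function(t, y, parms) list(rhs(t, y)),
                      parms = NULL, method = method,
                      rtol = 1e-8, atol = 1e-10)
  m <- unname(as.matrix(out[, -1]))
  colnames(m) <- c("S", "M", "H", "Y", "Z", "D", "T")
  m
}
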