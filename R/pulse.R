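#' Exogenous input pulse
#'
#' Piecewise input used for Factor A, Factor B and exogenous rescue/injection
#' inputs: zero before onset, a constant plateau on \code{[t_on, t_off]}, and
#' exponential decay afterwards. A constant input is obtained with
#' \code{t_off = Inf} (or \code{decay_rate = 0}).
#'
#' @param amplitude plateau level (nM), non-negative.
#' @param t_on onset time (hpf).
#' @param t_off end of plateau (hpf), may be \code{Inf}.
#' @param decay_rate first-order decay rate (1/hr) applied after \code{t_off}.
#' @return object of class \code{grn_pulse}.
#' @examples
#' p <- pulse(1, t_on = 12, t_off = 30, decay_rate = 0.2)
#' pulse_value(c(10, 20, 35), p)
#' @export
pulse <- function(amplitude, t_on = 0, t_off = Inf, decay_rate = 0) {
  stopifnot(length(amplitude) == 1, length(t_on) == 1, length(t_off) == 1,
            length(decay_rate) == 1)
  if (amplitude < 0) stop("pulse: amplitude must be non-negative")
  if (decay_rate < 0) stop("pulse: decay_rate must be non-negative")
  if (t_on > t_off) stop("pulse: t_on must not exceed t_off")
  structure(list(amplitude = amplitude, t_on = t_on, t_off = t_off,
                 decay_rate = decay_rate),
            class = "grn_pulse")
}

#' Evaluate a pulse input at given times
#'
#' @param t times (hpf), any finite vector.
#' @param p a \code{\link{pulse}}, or \code{NULL} (treated as identically 0).
#' @return input level (nM) at each time; continuous at \code{t_off}.
#' @export
pulse_value <- function(t, p) {
  if (is.null(p)) return(rep(0, length(t)))
  stopifnot(inherits(p, "grn_pulse"))
  out <- numeric(length(t))
  on <- t >= p$t_on & t <= p$t_off
  out[on] <- p$amplitude
  after <- t > p$t_off
  if (any(after)) {
    out[after] <- p$amplitude * exp(-p$decay_rate * (t[after] - p$t_off))
  }
  out
}

#' @export
print.grn_pulse <- function(x, ...) {
  cat(sprintf("<pulse> amplitude %g nM on [%g, %g] hpf, decay %g /hr\n",
              x$amplitude, x$t_on, x$t_off, x$decay_rate))
  invisible(x)
}
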