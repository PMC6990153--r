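## Method 1: direct, simulation-free inversion of the summary curves.
##
## The steady state of each gate is an exact Boltzmann sigmoid in the model
## parameterization: a_inf(V) = 1/(1 + exp(s_a (h_a - V))) with
## s_a = p2 + p4 and h_a = (log p3 - log p1)/s_a, and analogously
## r_inf with s_r = -(p6 + p8) and h_r = log(p5/p7)/s_r. Because
## a_inf/tau_a = k1 = p1 exp(p2 V) and r_inf/tau_r = k4 = p7 exp(-p8 V)
## identically, a log-linear regression of the reconstructed steady state
## divided by the measured time constants recovers the rate pre-factor and
## sensitivity, and the Boltzmann constraints then yield the remaining two
## parameters by back-substitution. Only the conductance needs one
## simulation (of Pr5) for its closed-form least-squares scaling.

#' Boltzmann sigmoid fit
#'
#' Least-squares fit of `1 / (1 + exp(s * (h - V)))` to (voltage, value)
#' points. The same sign convention is used for both gates: `s > 0` gives
#' an increasing (activation-type) curve, `s < 0` a decreasing
#' (inactivation-type) one; `direction` fixes the sign. Initialized by a
#' logit-scale linear regression (exact on noise-free data) and refined by
#' Nelder-Mead on the sum of squared errors.
#'
#' @param points data.frame with columns `voltage`, `value`.
#' @param direction "increasing" or "decreasing".
#' @return list with midpoint `h` (mV), slope factor `s` (mV^-1) and `rss`.
#' @export
fit_boltzmann <- function(points, direction = c("increasing", "decreasing")) {
  direction <- match.arg(direction)
  v <- points$voltage; y <- points$value
  if (length(v) < 3) stop("need at least 3 points")
  if (diff(range(y)) < 1e-12) stop("degenerate data: all values equal")
  ## logit-regression start (clamp away from 0/1 for the transform only)
  yc <- pmin(1 - 1e-10, pmax(1e-10, y))
  fit0 <- stats::lm.fit(cbind(1, v), log(yc / (1 - yc)))
  s0 <- fit0$coefficients[2]
  s0 <- if (direction == "increasing") max(s0, 1e-4) else min(s0, -1e-4)
  h0 <- -fit0$coefficients[1] / s0
  sse <- function(par) {
    s <- if (direction == "increasing") exp(par[2]) else -exp(par[2])
    sum((1 / (1 + exp(s * (par[1] - v))) - y)^2)
  }
  opt <- optim(c(h0, log(abs(s0))), sse, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-15))
  ## polish: a second restart guards against simplex stalls
  opt <- optim(opt$par, sse, method = "Nelder-Mead",
               control = list(maxit = 2000, reltol = 1e-15))
  s <- if (direction == "increasing") exp(opt$par[2]) else -exp(opt$par[2])
  list(h = unname(opt$par[1]), s = unname(s), rss = opt$value)
}

#' Activation rate parameters from summary data
#'
#' Ordinary least squares of `log(a_inf(V) / tau_act(V))` against `V`
#' (using the fitted Boltzmann steady state rather than the measured
#' points, which reduces noise) gives `log p1` and `p2`; the Boltzmann
#' constraints `s_a = p2 + p4` and `p3 = p1 exp(s_a h_a)` give the rest.
#'
#' @param boltz Boltzmann fit of the activation curve ([fit_boltzmann]).
#' @param tau_act data.frame(voltage, value) of activation time constants.
#' @return named vector p1..p4.
#' @export
activation_rates_from_summary <- function(boltz, tau_act) {
  if (nrow(tau_act) < 2) stop("need at least 2 activation time constants")
  v <- tau_act$voltage
  a_inf <- 1 / (1 + exp(boltz$s * (boltz$h - v)))
  fit <- stats::lm.fit(cbind(1, v), log(a_inf / tau_act$value))
  p1 <- exp(unname(fit$coefficients[1]))
  p2 <- unname(fit$coefficients[2])
  p4 <- boltz$s - p2
  p3 <- p1 * exp(boltz$s * boltz$h)
  out <- c(p1 = p1, p2 = p2, p3 = p3, p4 = p4)
  if (any(!is.finite(out)) || any(out <= 0))
    stop("positivity violation in activation back-substitution: ",
         paste(sprintf("%s=%.3g", names(out), out), collapse = ", "))
  out
}

#' Inactivation rate parameters from summary data
#'
#' As [activation_rates_from_summary] with the sign changes appropriate
#' for a decreasing steady state: regression of
#' `log(r_inf(V) / tau_inact(V))` on `V` gives `log p7` and `-p8`, then
#' `p6 = -s_r - p8` and `p5 = p7 exp(s_r h_r)`.
#'
#' @param boltz Boltzmann fit of the inactivation curve (decreasing).
#' @param tau_inact data.frame(voltage, value) of inactivation taus.
#' @return named vector p5..p8.
#' @export
inactivation_rates_from_summary <- function(boltz, tau_inact) {
  if (nrow(tau_inact) < 2) stop("need at least 2 inactivation time constants")
  v <- tau_inact$voltage
  r_inf <- 1 / (1 + exp(boltz$s * (boltz$h - v)))
  fit <- stats::lm.fit(cbind(1, v), log(r_inf / tau_inact$value))
  p7 <- exp(unname(fit$coefficients[1]))
  p8 <- -unname(fit$coefficients[2])
  p6 <- -boltz$s - p8
  p5 <- p7 * exp(boltz$s * boltz$h)
  out <- c(p5 = p5, p6 = p6, p7 = p7, p8 = p8)
  if (any(!is.finite(out)) || any(out <= 0))
    stop("positivity violation in inactivation back-substitution: ",
         paste(sprintf("%s=%.3g", names(out), out), collapse = ", "))
  out
}

#' Conductance from the Pr5 IV curve
#'
#' With the kinetics fixed, the simulated IV curve is proportional to the
#' conductance, so the scaling that minimizes the sum of squared errors
#' against the cell's IV curve is the closed-form linear least-squares
#' ratio.
#'
#' @param kinetics vector p1..p8 (any positive p9 placeholder is ignored).
#' @param iv_cell data.frame(voltage, value): the cell's IV curve.
#' @param protocol the Pr5 protocol.
#' @param conditions an [ionic_conditions] object.
#' @return scalar p9.
#' @export
conductance_from_iv <- function(kinetics, iv_cell, protocol,
                                conditions = ionic_conditions()) {
  p_unit <- ikr_params(c(unname(kinetics[1:8]), 1))
  traces <- simulate_step(p_unit, protocol, conditions)
  iv_sim <- analyse_pr5_iv(traces, protocol)
  if (all(iv_sim$value == 0)) stop("degenerate: simulated IV identically zero")
  ord <- match(round(iv_cell$voltage, 6), round(iv_sim$voltage, 6))
  if (anyNA(ord)) stop("IV voltage grids do not match")
  s <- iv_sim$value[ord]
  g <- sum(s * iv_cell$value) / sum(s * s)
  if (!is.finite(g) || g <= 0)
    stop("conductance estimate non-positive or non-finite")
  g
}

## IV-only extraction (avoids the exponential fits when only the peak
## currents are needed)
analyse_pr5_iv <- function(traces, protocol) {
  v <- vapply(seq_along(traces), function(i)
    .p_label_value(protocol, i, "P2")$voltage, 0)
  pk <- vapply(seq_along(traces), function(i) {
    sd <- .seg_data(traces[[i]], protocol, i, "P2")
    .peak_current(sd$current, sd$dt)
  }, 0)
  data.frame(voltage = v, value = pk)[order(v), ]
}

#' Direct summary-curve fit (method 1)
#'
#' Deterministic composition of the Boltzmann fits, the two log-linear
#' rate regressions and the conductance scaling. Exact (to floating
#' precision) when the summary curves equal the model's own steady states
#' and time constants.
#'
#' @param summary an `ikr_summary` for the cell.
#' @param protocol the Pr5 protocol (for the conductance simulation).
#' @param conditions an [ionic_conditions] object.
#' @return an [ikr_params] vector.
#' @export
method1_fit <- function(summary, protocol, conditions = ionic_conditions()) {
  ba <- fit_boltzmann(summary$act_ss, "increasing")
  br <- fit_boltzmann(summary$inact_ss, "decreasing")
  act <- activation_rates_from_summary(ba, summary$tau_act)
  inact <- inactivation_rates_from_summary(br, summary$tau_inact)
  p9 <- conductance_from_iv(c(act, inact), summary$iv, protocol, conditions)
  ikr_params(c(unname(act), unname(inact), p9))
}

#' Numerical-optimization variant of method 1
#'
#' Minimizes the summary-curve error measure `E_M1` over p1..p8 with
#' bounded, log-transformed CMA-ES (the conductance does not enter `E_M1`
#' and is set by [conductance_from_iv] afterwards).
#'
#' @inheritParams method1_fit
#' @param bounds a [parameter_bounds] object.
#' @param config optimizer configuration, see [cmaes_config].
#' @param seed integer seed.
#' @param start optional starting parameters (e.g. the [method1_fit]
#'   result); random when NULL.
#' @export
method1_numeric <- function(summary, protocol,
                            conditions = ionic_conditions(),
                            bounds = parameter_bounds(),
                            config = cmaes_config(), seed = 1,
                            start = NULL) {
  cell <- list(summary = summary, conditions = conditions)
  obj <- function(p) e_m1(p, cell)
  fit <- run_fit(obj, bounds, search_transform(), config, seed = seed,
                 start = start)
  p9 <- conductance_from_iv(fit$params[1:8], summary$iv, protocol, conditions)
  ikr_params(c(unname(fit$params[1:8]), p9))
}
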