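#' Voltage-dependent transition rates
#'
#' Eyring-style exponential voltage dependence of the four transition
#' rates. Vectorized over `V`. Exponents with magnitude above 700 are
#' reported as an invalid evaluation (error) rather than returning `Inf`,
#' so that objective functions can map them to an out-of-bounds sentinel.
#'
#' @param params an [ikr_params] vector.
#' @param V membrane potential(s), mV.
#' @return data.frame with columns k1..k4 (ms^-1).
#' @export
transition_rates <- function(params, V) {
  validate_params(params)
  stopifnot(all(is.finite(V)))
  ex <- cbind(params[2] * V, -params[4] * V, params[6] * V, -params[8] * V)
  if (any(abs(ex) > 700))
    stop("invalid rate evaluation: exponent overflow at extreme voltage")
  data.frame(k1 = params[1] * exp(ex[, 1]), k2 = params[3] * exp(ex[, 2]),
             k3 = params[5] * exp(ex[, 3]), k4 = params[7] * exp(ex[, 4]))
}

#' Steady states and time constants of the two gates
#'
#' \eqn{\tau_a = 1/(k_1+k_2)}, \eqn{a_\infty = k_1 \tau_a} for the
#' activation gate and \eqn{\tau_r = 1/(k_3+k_4)},
#' \eqn{r_\infty = k_4 \tau_r} for the inactivation (recovery) gate.
#' Vectorized over `V`.
#'
#' @inheritParams transition_rates
#' @return data.frame with columns a_inf, r_inf, tau_a, tau_r.
#' @export
gate_summary <- function(params, V) {
  k <- transition_rates(params, V)
  tau_a <- 1 / (k$k1 + k$k2)
  tau_r <- 1 / (k$k3 + k$k4)
  data.frame(a_inf = k$k1 * tau_a, r_inf = k$k4 * tau_r,
             tau_a = tau_a, tau_r = tau_r)
}

#' Instantaneous IKr current
#'
#' \eqn{I = p_9\, a\, r\, (V - E_K)}.
#'
#' @inheritParams transition_rates
#' @param a,r gate values in `[0, 1]`.
#' @param E_K reversal potential, mV.
#' @export
ikr_current <- function(params, a, r, V, E_K) {
  validate_params(params)
  params[[9]] * a * r * (V - E_K)
}

#' Gating ODE right-hand side
#'
#' \eqn{da/dt = (a_\infty - a)/\tau_a}, \eqn{dr/dt = (r_\infty - r)/\tau_r}
#' at fixed voltage `V`.
#'
#' @inheritParams transition_rates
#' @param state numeric `c(a, r)`.
#' @return numeric `c(da_dt, dr_dt)` in ms^-1.
#' @export
ode_rhs <- function(params, V, state) {
  g <- gate_summary(params, V)
  c(da_dt = (g$a_inf - state[[1]]) / g$tau_a,
    dr_dt = (g$r_inf - state[[2]]) / g$tau_r)
}

#' Exact gate relaxation at fixed voltage
#'
#' Both gates relax mono-exponentially at fixed voltage:
#' \eqn{a(t) = a_\infty + (a_0 - a_\infty) e^{-t/\tau_a}} and likewise
#' for `r`. Vectorized over `t`.
#'
#' @inheritParams ode_rhs
#' @param state numeric `c(a0, r0)`, the state at `t = 0`.
#' @param t elapsed time(s), ms, non-negative.
#' @return data.frame with columns a, r, t.
#' @export
analytic_step_solution <- function(params, V, state, t) {
  stopifnot(all(t >= 0))
  g <- gate_summary(params, V)
  data.frame(a = g$a_inf + (state[[1]] - g$a_inf) * exp(-t / g$tau_a),
             r = g$r_inf + (state[[2]] - g$r_inf) * exp(-t / g$tau_r),
             t = t)
}

#' Model-variable summary curves on given voltage grids
#'
#' Evaluates the model's own steady states and time constants on the
#' voltage grids of a summary set: the "ideal" summary curves that the
#' direct summary fit inverts exactly, and that the summary-curve
#' objective compares against extracted data.
#'
#' @inheritParams transition_rates
#' @param grids a list with numeric voltage vectors `act_ss`, `inact_ss`,
#'   `tau_act`, `tau_inact` (each in mV), e.g. from [summary_grids()].
#' @return a `summary_set` (without an IV curve unless supplied).
#' @export
analytic_summary <- function(params, grids) {
  cs <- function(v, val) data.frame(voltage = v, value = val)
  new_summary_set(
    act_ss = cs(grids$act_ss, gate_summary(params, grids$act_ss)$a_inf),
    inact_ss = cs(grids$inact_ss, gate_summary(params, grids$inact_ss)$r_inf),
    tau_act = cs(grids$tau_act, gate_summary(params, grids$tau_act)$tau_a),
    tau_inact = cs(grids$tau_inact, gate_summary(params, grids$tau_inact)$tau_r),
    iv = grids$iv %||% NULL)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
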