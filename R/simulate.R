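## Trace container and the two simulation routes: exact piecewise-analytic
## propagation for step protocols and adaptive Dormand-Prince integration
## (dense output, forced restarts at voltage discontinuities) for protocols
## containing sinusoid or sampled-waveform segments.

new_trace <- function(time, voltage, current, mask, protocol, sweep) {
  structure(data.frame(time_ms = time, voltage_mV = voltage, current = current),
            mask = mask, protocol = protocol, sweep = sweep,
            class = c("ikr_trace", "data.frame"))
}

#' @export
print.ikr_trace <- function(x, ...) {
  cat(sprintf("Trace: %s sweep %s, %d samples, %d masked\n",
              attr(x, "protocol"), attr(x, "sweep"), nrow(x),
              sum(!attr(x, "mask"))))
  invisible(x)
}

trace_mask <- function(trace) attr(trace, "mask")

sweep_sample_times <- function(protocol, sweep, dt = protocol$dt) {
  n <- round(sweep_duration(protocol, sweep) / dt)
  (seq_len(n) - 1) * dt
}

sweep_start_state <- function(params, segs) {
  v0 <- segment_voltage_at(segs[[1]], 0)
  g <- gate_summary(params, v0)
  c(g$a_inf, g$r_inf)
}

encode_sweep_ode <- function(segs) {
  nseg <- length(segs)
  kind <- integer(nseg); dur <- numeric(nseg)
  parmat <- matrix(0, nseg, 10)
  samp_t <- numeric(0); samp_v <- numeric(0)
  samp_off <- integer(nseg); samp_n <- integer(nseg)
  for (k in seq_len(nseg)) {
    s <- segs[[k]]
    dur[k] <- s$duration
    if (s$kind == "step") {
      kind[k] <- 0L; parmat[k, 1] <- s$voltage
    } else if (s$kind == "sine") {
      kind[k] <- 1L
      parmat[k, ] <- c(s$offset, rbind(s$amplitudes, s$omegas, s$phases))
    } else {
      kind[k] <- 2L
      samp_off[k] <- length(samp_t)
      samp_n[k] <- length(s$times)
      samp_t <- c(samp_t, s$times); samp_v <- c(samp_v, s$voltages)
    }
  }
  list(kind = kind, dur = dur, parmat = parmat, samp_t = samp_t,
       samp_v = samp_v, samp_off = samp_off, samp_n = samp_n)
}

#' Simulate a step protocol with the exact analytic solution
#'
#' Gates are propagated segment by segment with the exact
#' mono-exponential relaxation at each fixed voltage; state carries across
#' segments and each sweep starts from the steady state at its first
#' segment's voltage. Only valid for protocols made entirely of constant
#' steps.
#'
#' @param params an [ikr_params] vector.
#' @param protocol an `ikr_protocol` with only step segments.
#' @param conditions an [ionic_conditions] object.
#' @param dt sampling interval, ms.
#' @param want_state also return gate trajectories (columns a, r).
#' @return list of `ikr_trace`, one per sweep.
#' @export
simulate_step <- function(params, protocol, conditions = ionic_conditions(),
                          dt = protocol$dt, want_state = FALSE) {
  validate_params(params)
  masks <- capacitance_mask(protocol, dt = dt)
  lapply(seq_along(protocol$sweeps), function(i) {
    segs <- protocol$sweeps[[i]]
    kinds <- vapply(segs, function(s) s$kind, "")
    if (!all(kinds == "step"))
      stop("simulate_step requires a protocol of constant steps only; ",
           "use simulate_ode for '", protocol$name, "'")
    y0 <- sweep_start_state(params, segs)
    out <- cpp_sim_analytic(unclass(params),
                            vapply(segs, function(s) s$voltage, 0),
                            vapply(segs, function(s) s$duration, 0),
                            dt, conditions$E_K, y0[1], y0[2], want_state)
    if (!isTRUE(out$ok))
      stop("simulation failed (invalid rate evaluation) for parameters")
    tt <- sweep_sample_times(protocol, i, dt)
    tr <- new_trace(tt, voltage_at(protocol, i, tt), out$current,
                    masks[[i]], protocol$name, i)
    if (want_state) { tr$a <- out$a; tr$r <- out$r }
    tr
  })
}

#' Simulate any protocol by adaptive ODE integration
#'
#' Dormand-Prince 5(4) with dense output on the `dt` grid; voltage
#' discontinuities (segment boundaries, sampled-waveform nodes) are forced
#' integrator restart points. Low tolerances (default 1e-8) keep objective
#' functions free of solver noise; lax tolerances reproduce the
#' characteristic evaluation jitter of adaptive solvers.
#'
#' @inheritParams simulate_step
#' @param rtol,atol relative / absolute integration tolerances.
#' @export
simulate_ode <- function(params, protocol, conditions = ionic_conditions(),
                         dt = protocol$dt, rtol = 1e-8, atol = 1e-8,
                         want_state = FALSE) {
  validate_params(params)
  masks <- capacitance_mask(protocol, dt = dt)
  lapply(seq_along(protocol$sweeps), function(i) {
    segs <- protocol$sweeps[[i]]
    enc <- encode_sweep_ode(segs)
    y0 <- sweep_start_state(params, segs)
    tt <- sweep_sample_times(protocol, i, dt)
    vout <- voltage_at(protocol, i, tt)
    out <- cpp_sim_ode(unclass(params), enc$kind, enc$dur, enc$parmat,
                       enc$samp_t, enc$samp_v, enc$samp_off, enc$samp_n,
                       dt, conditions$E_K, rtol, atol, y0[1], y0[2],
                       want_state, vout)
    if (!isTRUE(out$ok))
      stop("ODE integration failed for parameter set")
    tr <- new_trace(tt, vout, out$current,
                    masks[[i]], protocol$name, i)
    if (want_state) { tr$a <- out$a; tr$r <- out$r }
    tr
  })
}

#' Simulate with the appropriate solver
#'
#' Analytic propagation for pure step protocols, adaptive ODE integration
#' otherwise.
#'
#' @inheritParams simulate_ode
#' @export
simulate_protocol <- function(params, protocol,
                              conditions = ionic_conditions(),
                              dt = protocol$dt, rtol = 1e-8, atol = 1e-8,
                              want_state = FALSE) {
  kinds <- unlist(lapply(protocol$sweeps, function(sw)
    vapply(sw, function(s) s$kind, "")))
  if (all(kinds == "step"))
    simulate_step(params, protocol, conditions, dt, want_state)
  else
    simulate_ode(params, protocol, conditions, dt, rtol, atol, want_state)
}

#' Trace CSV input/output
#'
#' CSV with header columns `time_ms`, `voltage_mV`, `current`; round-trips
#' to 12 significant digits.
#'
#' @param trace an `ikr_trace`.
#' @param path file path.
#' @export
write_trace <- function(trace, path) {
  df <- data.frame(time_ms = sprintf("%.12g", trace$time_ms),
                   voltage_mV = sprintf("%.12g", trace$voltage_mV),
                   current = sprintf("%.12g", trace$current))
  write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_trace
#' @export
read_trace <- function(path) {
  df <- tryCatch(read.csv(path), error = function(e)
    stop("cannot read trace: ", conditionMessage(e)))
  need <- c("time_ms", "voltage_mV", "current")
  if (!all(need %in% names(df)))
    stop("trace file must have columns time_ms, voltage_mV, current")
  if (nrow(df) == 0) stop("empty trace file")
  new_trace(df$time_ms, df$voltage_mV, df$current,
            rep(TRUE, nrow(df)), "file", 1)
}
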