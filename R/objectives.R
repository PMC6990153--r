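## The scalar error measures. All are sums of (normalized) RMSEs computed
## over mask-retained samples only; normalizations use the cell's own
## (mask-retained) data so values are comparable across cells. Simulation
## or summary-derivation failures map to +Inf, which the bounded optimizer
## treats like an out-of-bounds proposal.

#' Cell dataset container
#'
#' Bundles everything the error measures need for one cell: current traces
#' per protocol, the extracted summary curves, and the ionic conditions
#' (hence E_K). The protocols used to record/simulate the traces travel
#' with the dataset so objectives can resimulate them.
#'
#' @param id cell identifier.
#' @param traces named list (Pr2..Pr7) of lists of `ikr_trace`.
#' @param summary an `ikr_summary`.
#' @param conditions an [ionic_conditions] object.
#' @param protocols named list of `ikr_protocol`s matching `traces`.
#' @export
cell_dataset <- function(id, traces, summary, conditions, protocols) {
  structure(list(id = id, traces = traces, summary = summary,
                 conditions = conditions, protocols = protocols),
            class = "ikr_cell")
}

#' @export
print.ikr_cell <- function(x, ...) {
  cat(sprintf("Cell %s: protocols %s\n", x$id,
              paste(names(x$traces), collapse = ", ")))
  print(x$summary)
  invisible(x)
}

#' Root mean-squared error
#' @param x,y equal-length numeric vectors.
#' @export
rmse <- function(x, y) {
  if (length(x) != length(y)) stop("length mismatch")
  if (length(x) == 0) stop("empty vectors")
  sqrt(mean((x - y)^2))
}

## RMSE between two (voltage, value) curves; Inf if the grids differ
.curve_rmse <- function(cell_curve, sim_curve) {
  if (is.null(cell_curve) || is.null(sim_curve)) return(Inf)
  if (nrow(cell_curve) != nrow(sim_curve)) return(Inf)
  if (max(abs(cell_curve$voltage - sim_curve$voltage)) > 1e-6) return(Inf)
  rmse(cell_curve$value, sim_curve$value)
}

#' Direct summary-curve error E_M1
#'
#' Weighted sum of RMSEs between the cell's summary curves and the model's
#' own steady states and time constants evaluated analytically at the same
#' voltages (no simulation). Time-constant terms are normalized by the
#' cell's largest value; the steady states are already in [0, 1].
#' Independent of the conductance p9.
#'
#' @param params an [ikr_params] vector (or positive numeric of length 9).
#' @param cell a [cell_dataset] (only `summary` is used).
#' @export
e_m1 <- function(params, cell) {
  s <- cell$summary
  g <- function(v) gate_summary(params, v)
  r <- tryCatch({
    rmse(s$act_ss$value, g(s$act_ss$voltage)$a_inf) +
      rmse(s$inact_ss$value, g(s$inact_ss$voltage)$r_inf) +
      rmse(s$tau_act$value, g(s$tau_act$voltage)$tau_a) / max(s$tau_act$value) +
      rmse(s$tau_inact$value, g(s$tau_inact$voltage)$tau_r) / max(s$tau_inact$value)
  }, error = function(e) Inf)
  r
}

#' Simulated summary-curve error E_M2
#'
#' Simulates Pr2-Pr5, derives summary curves with the identical extraction
#' pipeline used on the measured data, and sums the RMSEs of the activation
#' curve, both time-constant curves (normalized by the cell's maxima) and
#' the IV curve (normalized by the cell's IV range). The IV curve is used
#' instead of the steady state of inactivation: same data points, no
#' near-E_K numerical trouble, and it carries the conductance. Any
#' simulation or summary-derivation failure yields +Inf.
#'
#' @inheritParams e_m1
#' @param protocols,conditions defaults taken from the cell.
#' @export
e_m2 <- function(params, cell, protocols = cell$protocols,
                 conditions = cell$conditions) {
  s <- cell$summary
  sim_sum <- tryCatch(suppressWarnings({
    tr <- list(Pr2 = simulate_step(params, protocols$Pr2, conditions),
               Pr3 = simulate_step(params, protocols$Pr3, conditions),
               Pr4 = simulate_step(params, protocols$Pr4, conditions),
               Pr5 = simulate_step(params, protocols$Pr5, conditions))
    assemble_summary(tr, protocols, conditions)
  }), error = function(e) NULL)
  if (is.null(sim_sum)) return(Inf)
  iv_rng <- diff(range(s$iv$value))
  .curve_rmse(s$act_ss, sim_sum$act_ss) +
    .curve_rmse(s$tau_act, sim_sum$tau_act) / max(s$tau_act$value) +
    .curve_rmse(s$tau_inact, sim_sum$tau_inact) / max(s$tau_inact$value) +
    .curve_rmse(s$iv, sim_sum$iv) / iv_rng
}

## precompute everything that does not depend on the candidate parameters
.whole_trace_pre <- function(cell, protocol_names) {
  pre <- list()
  for (nm in protocol_names) {
    prot <- cell$protocols[[nm]]
    trs <- cell$traces[[nm]]
    if (is.null(prot) || is.null(trs)) stop("cell lacks protocol ", nm)
    kinds <- unlist(lapply(prot$sweeps, function(sw)
      vapply(sw, function(s) s$kind, "")))
    analytic <- all(kinds == "step")
    masks <- lapply(trs, function(tr) attr(tr, "mask"))
    if (analytic) {
      segv <- segd <- numeric(0); seg_off <- seg_n <- integer(0)
      midx <- integer(0); moff <- mn <- integer(0)
      cellI <- vector("list", length(trs))
      for (i in seq_along(prot$sweeps)) {
        segs <- prot$sweeps[[i]]
        seg_off <- c(seg_off, length(segv))
        seg_n <- c(seg_n, length(segs))
        segv <- c(segv, vapply(segs, function(s) s$voltage, 0))
        segd <- c(segd, vapply(segs, function(s) s$duration, 0))
        mi <- which(masks[[i]]) - 1L
        moff <- c(moff, length(midx)); mn <- c(mn, length(mi))
        midx <- c(midx, mi)
        cellI[[i]] <- trs[[i]]$current[masks[[i]]]
      }
      cellI <- unlist(cellI)
      pre[[nm]] <- list(analytic = TRUE, segv = segv, segd = segd,
                        seg_off = seg_off, seg_n = seg_n, midx = midx,
                        moff = moff, mn = mn, cellI = cellI,
                        rng = diff(range(cellI)), dt = prot$dt)
    } else {
      sw <- lapply(seq_along(prot$sweeps), function(i) {
        segs <- prot$sweeps[[i]]
        list(enc = encode_sweep_ode(segs),
             vout = trs[[i]]$voltage_mV,
             v0 = segment_voltage_at(segs[[1]], 0),
             widx = which(masks[[i]]) - 1L,
             cellI = trs[[i]]$current[masks[[i]]])
      })
      nall <- sum(vapply(sw, function(s) length(s$widx), 0L))
      rng <- diff(range(unlist(lapply(sw, function(s) s$cellI))))
      pre[[nm]] <- list(analytic = FALSE, sweeps = sw, n = nall,
                        rng = rng, dt = prot$dt)
    }
  }
  pre$E_K <- cell$conditions$E_K
  pre
}

## lean steady state at one voltage (no data.frame, overflow -> NULL)
.steady_state0 <- function(p, V) {
  ex <- c(p[2], -p[4], p[6], -p[8]) * V
  if (any(abs(ex) > 700)) return(NULL)
  k <- c(p[1], p[3], p[5], p[7]) * exp(ex)
  out <- c(k[1] / (k[1] + k[2]), k[4] / (k[3] + k[4]))
  if (any(!is.finite(out))) NULL else out
}

.whole_trace_eval <- function(params, pre, protocol_names,
                              rtol = 1e-8, atol = 1e-8) {
  p <- as.numeric(params)
  total <- 0
  for (nm in protocol_names) {
    pp <- pre[[nm]]
    if (pp$analytic) {
      out <- cpp_step_protocol_ssq(p, pp$segv, pp$segd, pp$seg_off,
                                   pp$seg_n, pp$midx, pp$moff, pp$mn,
                                   pp$cellI, pp$dt, pre$E_K)
      if (!isTRUE(out$ok)) return(Inf)
      total <- total + sqrt(out$ssq / out$n) / pp$rng
    } else {
      ssq <- 0
      for (sw in pp$sweeps) {
        y0 <- .steady_state0(p, sw$v0)
        if (is.null(y0)) return(Inf)
        out <- cpp_sim_ode(p, sw$enc$kind, sw$enc$dur, sw$enc$parmat,
                           sw$enc$samp_t, sw$enc$samp_v, sw$enc$samp_off,
                           sw$enc$samp_n, pp$dt, pre$E_K, rtol, atol,
                           y0[1], y0[2], FALSE, sw$vout)
        if (!isTRUE(out$ok)) return(Inf)
        ssq <- ssq + cpp_ssq_idx(out$current, sw$cellI, sw$widx)
      }
      total <- total + sqrt(ssq / pp$n) / pp$rng
    }
  }
  total
}

#' Whole-trace error E_M3 over the step protocols
#'
#' Sum over Pr2-Pr5 of the RMSE between the cell's and the simulated
#' current traces (mask-retained samples only), each normalized by the
#' range of that protocol's cell current. Simulated analytically
#' (piecewise-exponential), so the objective carries no solver noise.
#'
#' @inheritParams e_m1
#' @export
e_m3 <- function(params, cell) {
  validate_params(params)
  .whole_trace_eval(params, .whole_trace_pre(cell, c("Pr2", "Pr3", "Pr4", "Pr5")),
                    c("Pr2", "Pr3", "Pr4", "Pr5"))
}

#' Whole-trace error E_M4 on the sinusoidal protocol
#'
#' Range-normalized RMSE of the Pr7 current; a single protocol, so no
#' per-protocol weighting choices arise.
#'
#' @inheritParams e_m1
#' @param rtol,atol ODE tolerances for the Pr7 simulation.
#' @export
e_m4 <- function(params, cell, rtol = 1e-8, atol = 1e-8) {
  validate_params(params)
  .whole_trace_eval(params, .whole_trace_pre(cell, "Pr7"), "Pr7",
                    rtol, atol)
}

#' Validation error E_AP on the AP-waveform protocol
#'
#' Range-normalized RMSE of the Pr6 (action-potential waveform clamp)
#' current. Pr6 is never used for fitting, so this is an independent
#' validation measure.
#'
#' @inheritParams e_m4
#' @export
e_ap <- function(params, cell, rtol = 1e-8, atol = 1e-8) {
  validate_params(params)
  .whole_trace_eval(params, .whole_trace_pre(cell, "Pr6"), "Pr6",
                    rtol, atol)
}

#' Multi-cell aggregate error
#'
#' Plain mean over cells; the per-cell normalizations built into each
#' measure make further weighting unnecessary.
#'
#' @param errors numeric vector of per-cell error values.
#' @export
e_all <- function(errors) mean(errors)

#' Fast objective factory for fitting
#'
#' Returns a closure `f(params) -> scalar` with all parameter-independent
#' work (protocol encodings, masked cell currents, normalization ranges)
#' precomputed; used by the optimization layer, where the objective is
#' evaluated thousands of times.
#'
#' @param cell a [cell_dataset].
#' @param method 1, 2, 3 or 4 (or "ap").
#' @export
make_objective <- function(cell, method) {
  if (method == 1) return(function(params) e_m1(params, cell))
  if (method == 2) return(function(params) e_m2(params, cell))
  nms <- if (method == 3) c("Pr2", "Pr3", "Pr4", "Pr5")
         else if (method == 4) "Pr7" else "Pr6"
  pre <- .whole_trace_pre(cell, nms)
  function(params) .whole_trace_eval(params, pre, nms)
}
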