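## Extraction of the five experimental summary curves from current traces:
## steady-state activation (from Pr3 tail peaks), steady-state inactivation
## and the peak IV curve (from Pr5 P2 currents), the activation time
## constant (Pr5 deactivation fits plus the single Pr2 envelope point) and
## the inactivation time constant (Pr5 fast-phase fits plus Pr4 onset
## fits). The identical pipeline is applied to measured and simulated
## traces, which is what the simulated-summary objective relies on.

new_summary_set <- function(act_ss, inact_ss, tau_act, tau_inact, iv) {
  structure(list(act_ss = act_ss, inact_ss = inact_ss, tau_act = tau_act,
                 tau_inact = tau_inact, iv = iv),
            class = "ikr_summary")
}

#' @export
print.ikr_summary <- function(x, ...) {
  n <- vapply(x, function(d) if (is.null(d)) 0L else nrow(d), 0L)
  cat("Summary curves (points): act_ss", n[1], "| inact_ss", n[2],
      "| tau_act", n[3], "| tau_inact", n[4], "| iv", n[5], "\n")
  invisible(x)
}

#' Voltage grids of a summary set
#' @param summary an `ikr_summary`.
#' @export
summary_grids <- function(summary) {
  lapply(summary[c("act_ss", "inact_ss", "tau_act", "tau_inact")],
         function(d) d$voltage)
}

#' Summary-curve CSV input/output
#'
#' Long format with columns `curve` (act_ss, inact_ss, tau_act, tau_inact,
#' iv), `voltage_mV` and `value` -- the format a literature-digitized
#' summary data set would arrive in.
#'
#' @param summary an `ikr_summary`.
#' @param path file path.
#' @export
write_summary <- function(summary, path) {
  rows <- do.call(rbind, lapply(names(summary), function(nm) {
    d <- summary[[nm]]
    if (is.null(d)) return(NULL)
    data.frame(curve = nm, voltage_mV = d$voltage, value = d$value)
  }))
  write.table(rows, path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_summary
#' @export
read_summary <- function(path) {
  df <- read.csv(path)
  get <- function(nm) {
    d <- df[df$curve == nm, ]
    if (nrow(d) == 0) return(NULL)
    data.frame(voltage = d$voltage_mV, value = d$value)
  }
  new_summary_set(get("act_ss"), get("inact_ss"), get("tau_act"),
                  get("tau_inact"), get("iv"))
}

## -------------------------------------------------------------------------
## Exponential fitting (profiled linear amplitudes, log-tau search)
## -------------------------------------------------------------------------

.exp_design_rss <- function(tt, yy, taus) {
  X <- cbind(1, vapply(taus, function(tau) exp(-tt / tau),
                       numeric(length(tt))))
  fit <- tryCatch(stats::lm.fit(X, yy), error = function(e) NULL)
  if (is.null(fit) || anyNA(fit$coefficients)) return(list(rss = Inf))
  list(rss = sum(fit$residuals^2), coef = fit$coefficients)
}

#' Fit one or two decaying exponentials
#'
#' Least-squares fit of `offset + amplitude * exp(-t / tau)` (one term per
#' phase). Amplitudes and offset are profiled out linearly; the time
#' constants are searched on a log scale (golden-section for one phase,
#' Nelder-Mead for two). Time constants are therefore positive by
#' construction. A signal whose range is below `floor` yields the no-fit
#' sentinel `NULL` with a warning, and the calling summary-extraction step
#' omits that point.
#'
#' @param times,values numeric vectors, times increasing, length >= 5.
#' @param n_phases 1 or 2. For 2 phases the returned list has elements
#'   `fast` and `slow` (taus ordered fast to slow).
#' @param floor minimal signal range for a fit to be attempted.
#' @param tau_range optional `c(min, max)` bounds for tau, ms.
#' @return an `ikr_expfit` (list: amplitude, tau, offset, rss), a list of
#'   two for `n_phases = 2`, or `NULL` (no-fit sentinel).
#' @export
fit_exponential <- function(times, values, n_phases = 1, floor = 1e-6,
                            tau_range = NULL) {
  stopifnot(length(times) == length(values), n_phases %in% 1:2)
  if (length(times) < 5) stop("need at least 5 samples")
  if (any(diff(times) <= 0)) stop("times must be increasing")
  if (diff(range(values)) < floor) {
    warning("signal range below floor; no exponential fit")
    return(NULL)
  }
  ## deterministic decimation: profiling the amplitudes is O(n) per tau
  ## candidate, and ~400 points constrain a 1-2 phase exponential as well
  ## as 50k do; applied identically to measured and simulated data.
  if (length(times) > 400) {
    sel <- unique(round(seq(1, length(times), length.out = 400)))
    times <- times[sel]; values <- values[sel]
  }
  tt <- times - times[1]
  span <- tt[length(tt)]
  if (is.null(tau_range)) tau_range <- c(span / 2000, span * 20)
  lo <- log(tau_range[1]); hi <- log(tau_range[2])

  if (n_phases == 1) {
    f1 <- function(ltau) .exp_design_rss(tt, values, exp(ltau))$rss
    grid <- seq(lo, hi, length.out = 21)
    g <- vapply(grid, f1, 0)
    i0 <- which.min(g)
    blo <- grid[max(1, i0 - 1)]; bhi <- grid[min(length(grid), i0 + 1)]
    opt <- optimize(f1, c(blo, bhi), tol = 1e-12)
    tau <- exp(opt$minimum)
    res <- .exp_design_rss(tt, values, tau)
    structure(list(amplitude = unname(res$coef[2]), tau = tau,
                   offset = unname(res$coef[1]), rss = res$rss),
              class = "ikr_expfit")
  } else {
    f2 <- function(lt) {
      if (any(lt < lo - 1e-9) || any(lt > hi + 1e-9)) return(Inf)
      .exp_design_rss(tt, values, exp(lt))$rss
    }
    start <- log(c(max(span / 50, tau_range[1] * 2),
                   min(span / 2, tau_range[2] / 2)))
    opt <- optim(start, f2, method = "Nelder-Mead",
                 control = list(maxit = 600, reltol = 1e-14))
    taus <- sort(exp(opt$par))
    res <- .exp_design_rss(tt, values, taus)
    if (!is.finite(res$rss)) {
      warning("two-phase exponential fit failed")
      return(NULL)
    }
    list(fast = structure(list(amplitude = unname(res$coef[2]), tau = taus[1],
                               offset = unname(res$coef[1]), rss = res$rss),
                          class = "ikr_expfit"),
         slow = structure(list(amplitude = unname(res$coef[3]), tau = taus[2],
                               offset = unname(res$coef[1]), rss = res$rss),
                          class = "ikr_expfit"))
  }
}

## -------------------------------------------------------------------------
## Per-protocol extraction
## -------------------------------------------------------------------------

## signed peak of largest magnitude after light smoothing (reduces the
## upward bias of raw extremum picking on noisy near-zero currents)
.peak_current <- function(values, dt, smooth_ms = 1) {
  w <- max(1L, round(smooth_ms / dt))
  if (w > 1 && length(values) > 2 * w) {
    sm <- as.numeric(stats::filter(values, rep(1 / w, w), sides = 2))
    sm[is.na(sm)] <- values[is.na(sm)]
  } else sm <- values
  sm[which.max(abs(sm))]
}

.seg_data <- function(trace, protocol, sweep, label) {
  idx <- sample_window(protocol, sweep, label)
  keep <- attr(trace, "mask")[idx]
  tt <- trace$time_ms[idx]
  list(t = tt[keep] - tt[1], current = trace$current[idx][keep],
       dt = protocol$dt)
}

.p_label_value <- function(protocol, sweep, label) {
  segs <- protocol$sweeps[[sweep]]
  k <- match(label, vapply(segs, function(s) s$label, ""))
  segs[[k]]
}

#' Activation time constant at +40 mV from Pr2
#'
#' Collects the peak tail current after each P1 duration and fits a single
#' exponential to the peak-versus-duration envelope; its time constant
#' estimates the activation time constant at the P1 voltage.
#'
#' @param traces list of `ikr_trace`, one per Pr2 sweep.
#' @param protocol the Pr2 protocol used to record them.
#' @return data.frame(voltage, value) with one row, or `NULL` when fewer
#'   than 4 usable peaks were found.
#' @export
tau_act_from_pr2 <- function(traces, protocol) {
  durs <- peaks <- numeric(0)
  for (i in seq_along(traces)) {
    sd <- .seg_data(traces[[i]], protocol, i, "tail")
    if (length(sd$current) < 5) next
    durs <- c(durs, .p_label_value(protocol, i, "P1")$duration)
    peaks <- c(peaks, .peak_current(sd$current, sd$dt))
  }
  if (length(peaks) < 4) {
    warning("fewer than 4 usable Pr2 tail peaks; no activation tau")
    return(NULL)
  }
  fit <- tryCatch(fit_exponential(durs, peaks, 1),
                  error = function(e) NULL, warning = function(w) NULL)
  if (is.null(fit)) {
    warning("Pr2 envelope fit failed")
    return(NULL)
  }
  data.frame(voltage = .p_label_value(protocol, 1, "P1")$voltage,
             value = fit$tau)
}

#' Steady-state activation curve from Pr3
#'
#' Peak tail current per sweep, normalized by the largest-magnitude peak
#' and clamped into `[0, 1]`, paired with the P1 voltages.
#'
#' @param traces list of `ikr_trace`, one per Pr3 sweep.
#' @param protocol the Pr3 protocol.
#' @param E_K reversal potential (unused in the default normalization but
#'   part of the extraction interface).
#' @export
act_ss_from_pr3 <- function(traces, protocol, E_K = NULL) {
  peaks <- vapply(seq_along(traces), function(i) {
    sd <- .seg_data(traces[[i]], protocol, i, "tail")
    .peak_current(sd$current, sd$dt)
  }, 0)
  if (all(peaks == 0)) stop("all Pr3 tail peaks are zero; extraction failed")
  ref <- peaks[which.max(abs(peaks))]
  v <- vapply(seq_along(traces), function(i)
    .p_label_value(protocol, i, "P1")$voltage, 0)
  data.frame(voltage = v, value = pmin(1, pmax(0, peaks / ref)))
}

#' Inactivation time constants from Pr4
#'
#' Single-exponential fit to the inactivating current onset during P3, for
#' every sweep whose P3 voltage is at or above -40 mV.
#'
#' @param traces list of `ikr_trace`, one per Pr4 sweep.
#' @param protocol the Pr4 protocol.
#' @export
tau_inact_from_pr4 <- function(traces, protocol) {
  out <- NULL
  for (i in seq_along(traces)) {
    v <- .p_label_value(protocol, i, "P3")$voltage
    if (v < -40) next
    sd <- .seg_data(traces[[i]], protocol, i, "P3")
    fit <- tryCatch(suppressWarnings(fit_exponential(sd$t, sd$current, 1)),
                    error = function(e) NULL)
    if (is.null(fit)) {
      warning("Pr4 onset fit failed at ", v, " mV; point omitted")
      next
    }
    out <- rbind(out, data.frame(voltage = v, value = fit$tau))
  }
  out
}

#' Time constants, steady-state inactivation and IV curve from Pr5
#'
#' Per sweep: the IV point is the signed peak current during P2; a
#' two-phase fit over the onset window yields the fast (recovery /
#' inactivation) time constant for P2 voltages below -30 mV; a
#' single-exponential fit over the remainder yields the slow (deactivation)
#' time constant for P2 voltages below 0 mV; the steady state of
#' inactivation is the peak current divided by the driving force,
#' normalized to a maximum of 1, with the P2 voltage nearest E_K excluded
#' (near-zero driving force makes the ratio numerically useless there).
#'
#' @param traces list of `ikr_trace`, one per Pr5 sweep.
#' @param protocol the Pr5 protocol.
#' @param E_K reversal potential, mV.
#' @param onset_ms length of the onset window used for the fast-phase fit.
#' @param slow_start_ms start of the deactivation-fit window within P2.
#' @export
analyse_pr5 <- function(traces, protocol, E_K, onset_ms = 300,
                        slow_start_ms = 50) {
  iv <- tau_a <- tau_r <- NULL
  volts <- vapply(seq_along(traces), function(i)
    .p_label_value(protocol, i, "P2")$voltage, 0)
  peaks <- numeric(length(traces))
  for (i in seq_along(traces)) {
    v <- volts[i]
    sd <- .seg_data(traces[[i]], protocol, i, "P2")
    peaks[i] <- .peak_current(sd$current, sd$dt)
    iv <- rbind(iv, data.frame(voltage = v, value = peaks[i]))
    if (v < -30) {
      on <- sd$t <= onset_ms
      fit <- tryCatch(suppressWarnings(
        fit_exponential(sd$t[on], sd$current[on], 2)),
        error = function(e) NULL)
      if (!is.null(fit))
        tau_r <- rbind(tau_r, data.frame(voltage = v, value = fit$fast$tau))
      else warning("Pr5 fast-phase fit failed at ", v, " mV; point omitted")
    }
    if (v < 0) {
      sl <- sd$t >= slow_start_ms
      fit <- tryCatch(suppressWarnings(
        fit_exponential(sd$t[sl], sd$current[sl], 1)),
        error = function(e) NULL)
      if (!is.null(fit))
        tau_a <- rbind(tau_a, data.frame(voltage = v, value = fit$tau))
      else warning("Pr5 deactivation fit failed at ", v, " mV; point omitted")
    }
  }
  drop <- which.min(abs(volts - E_K))
  rin_raw <- peaks / (volts - E_K)
  rin_raw <- rin_raw[-drop]
  rin_v <- volts[-drop]
  inact_ss <- data.frame(voltage = rin_v,
                         value = pmin(1, pmax(0, rin_raw / max(rin_raw))))
  list(tau_act = tau_a, tau_inact = tau_r, inact_ss = inact_ss, iv = iv)
}

#' Assemble the full summary set for one cell
#'
#' Runs all per-protocol extractions and merges them: the activation time
#' constants are the Pr5 deactivation fits plus the single Pr2 point; the
#' inactivation time constants are the Pr5 fast-phase fits plus the Pr4
#' onset fits; curves are sorted by voltage.
#'
#' @param traces named list with elements Pr2, Pr3, Pr4, Pr5, each a list
#'   of `ikr_trace`.
#' @param protocols named list of the corresponding `ikr_protocol`s.
#' @param conditions an [ionic_conditions] object.
#' @return an `ikr_summary`.
#' @export
assemble_summary <- function(traces, protocols, conditions) {
  need <- c("Pr2", "Pr3", "Pr4", "Pr5")
  if (!all(need %in% names(traces)) || !all(need %in% names(protocols)))
    stop("incomplete dataset: need traces and protocols for Pr2-Pr5")
  E_K <- conditions$E_K
  p2 <- tau_act_from_pr2(traces$Pr2, protocols$Pr2)
  a3 <- act_ss_from_pr3(traces$Pr3, protocols$Pr3, E_K)
  r4 <- tau_inact_from_pr4(traces$Pr4, protocols$Pr4)
  p5 <- analyse_pr5(traces$Pr5, protocols$Pr5, E_K)
  srt <- function(d) if (is.null(d)) d else d[order(d$voltage), , drop = FALSE]
  new_summary_set(act_ss = srt(a3),
                  inact_ss = srt(p5$inact_ss),
                  tau_act = srt(rbind(p5$tau_act, p2)),
                  tau_inact = srt(rbind(p5$tau_inact, r4)),
                  iv = srt(p5$iv))
}
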