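## Voltage-clamp protocol data model and the default Pr2-Pr7 builders.
##
## A protocol is an ordered list of sweeps; a sweep is an ordered list of
## segments. Segments are constant steps, sums of three sinusoids, or
## sampled waveforms (piecewise-linear interpolation between nodes).

#' Protocol building blocks
#'
#' `seg_step` is a constant-voltage step, `seg_sine` a sum of three
#' sinusoids around an offset, `seg_sampled` a piecewise-linear sampled
#' waveform (node times start at 0 and span the duration);
#' `new_protocol` assembles sweeps (lists of segments) into a protocol.
#'
#' @param duration segment duration, ms.
#' @param voltage step voltage, mV.
#' @param label optional segment role label (e.g. "P1", "tail").
#' @export
seg_step <- function(duration, voltage, label = "") {
  stopifnot(duration > 0, is.finite(voltage))
  list(kind = "step", duration = duration, voltage = voltage, label = label)
}

#' @rdname seg_step
#' @param offset sinusoid offset, mV.
#' @param amplitudes,omegas,phases length-3 vectors (mV, rad/ms, rad).
#' @export
seg_sine <- function(duration, offset, amplitudes, omegas, phases, label = "") {
  stopifnot(duration > 0, length(amplitudes) == 3, length(omegas) == 3,
            length(phases) == 3)
  list(kind = "sine", duration = duration, offset = offset,
       amplitudes = as.numeric(amplitudes), omegas = as.numeric(omegas),
       phases = as.numeric(phases), label = label)
}

#' @rdname seg_step
#' @param times,voltages waveform nodes (ms, mV).
#' @export
seg_sampled <- function(times, voltages, label = "") {
  times <- as.numeric(times); voltages <- as.numeric(voltages)
  if (length(times) < 2 || length(times) != length(voltages))
    stop("sampled segment needs >= 2 (time, voltage) nodes of equal length")
  if (any(diff(times) <= 0)) stop("sampled segment times must be strictly increasing")
  if (times[1] != 0) stop("sampled segment times must start at 0")
  list(kind = "sampled", duration = times[length(times)],
       times = times, voltages = voltages, label = label)
}

#' @rdname seg_step
#' @param name protocol name.
#' @param sweeps list of sweeps, each a list of segments.
#' @param dt sampling interval, ms.
#' @export
new_protocol <- function(name, sweeps, dt) {
  stopifnot(length(sweeps) >= 1, dt > 0)
  structure(list(name = name, sweeps = sweeps, dt = dt),
            class = "ikr_protocol")
}

#' @export
print.ikr_protocol <- function(x, ...) {
  cat(sprintf("Protocol %s: %d sweep(s), dt = %g ms, total %g ms\n",
              x$name, length(x$sweeps), x$dt, protocol_duration(x)))
  invisible(x)
}

#' Shipped default protocol configuration
#'
#' Reads the packaged protocol grid file (voltages, durations, sine
#' constants, sampling interval, blanking window). Pass a different path
#' to substitute corrected grids without touching code.
#'
#' @param path JSON configuration file.
#' @export
protocol_config <- function(path = system.file("extdata", "protocols.json",
                                               package = "ikrfit")) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Sweep and protocol durations (ms)
#' @param protocol an `ikr_protocol`.
#' @param sweep sweep index.
#' @export
sweep_duration <- function(protocol, sweep) {
  sum(vapply(protocol$sweeps[[sweep]], function(s) s$duration, 0))
}

#' @rdname sweep_duration
#' @export
protocol_duration <- function(protocol) {
  sum(vapply(seq_along(protocol$sweeps), function(i) sweep_duration(protocol, i), 0))
}

segment_voltage_limits <- function(seg) {
  switch(seg$kind,
    step = c(seg$voltage, seg$voltage),
    sine = c(seg$offset + sum(seg$amplitudes * sin(seg$phases)),
             seg$offset + sum(seg$amplitudes *
               sin(seg$omegas * seg$duration + seg$phases))),
    sampled = c(seg$voltages[1], seg$voltages[length(seg$voltages)]))
}

segment_voltage_at <- function(seg, s) {
  switch(seg$kind,
    step = rep(seg$voltage, length(s)),
    sine = seg$offset +
      seg$amplitudes[1] * sin(seg$omegas[1] * s + seg$phases[1]) +
      seg$amplitudes[2] * sin(seg$omegas[2] * s + seg$phases[2]) +
      seg$amplitudes[3] * sin(seg$omegas[3] * s + seg$phases[3]),
    sampled = stats::approx(seg$times, seg$voltages, xout = s, rule = 2)$y)
}

#' Commanded voltage at a given time
#'
#' Constant within step segments, analytic within sinusoid segments and
#' linearly interpolated within sampled segments. Samples falling exactly
#' on a segment boundary belong to the incoming segment.
#'
#' @inheritParams sweep_duration
#' @param t time(s) within the sweep, ms; `0 <= t < sweep_duration`.
#' @export
voltage_at <- function(protocol, sweep = 1, t) {
  segs <- protocol$sweeps[[sweep]]
  dur <- sweep_duration(protocol, sweep)
  if (any(t < 0 | t >= dur + 1e-9)) stop("t outside sweep duration")
  ends <- cumsum(vapply(segs, function(s) s$duration, 0))
  starts <- c(0, ends[-length(ends)])
  idx <- findInterval(t + 1e-9, c(0, ends), rightmost.closed = TRUE)
  idx[idx > length(segs)] <- length(segs)
  out <- numeric(length(t))
  for (k in unique(idx)) {
    sel <- idx == k
    out[sel] <- segment_voltage_at(segs[[k]], t[sel] - starts[k])
  }
  out
}

## -------------------------------------------------------------------------
## Builders for the default step protocols
## -------------------------------------------------------------------------

.pr_cfg <- function(name, config) {
  base <- protocol_config()
  cfg <- base[[name]]
  if (!is.null(config)) cfg <- modifyList(cfg, config)
  cfg$holding <- cfg$holding %||% base$holding
  cfg$dt <- cfg$dt %||% base$dt
  cfg
}

#' Build the default voltage-step and sine-wave protocols
#'
#' `build_pr2`: activation time constant at +40 mV; six sweeps with an
#' increasing P1 duration followed by a fixed hyperpolarized tail step.
#' `build_pr3`: steady-state activation; seven sweeps varying the P1
#' voltage with a long fixed P1 duration and a fixed tail.
#' `build_pr4`: inactivation time constants; sixteen sweeps varying the P3
#' voltage after a +40 mV activating step and a brief recovery step.
#' `build_pr5`: activation/inactivation time constants, steady-state
#' inactivation and the peak IV curve; nine sweeps varying the P2 voltage.
#' `build_pr7`: a single 8 s sweep: holding, a +40 mV step, a sum of three
#' sine waves (roughly 1, 6 and 30 Hz) and return to holding.
#'
#' @param config optional list overriding entries of the shipped
#'   configuration for this protocol (see [protocol_config()]).
#' @return an `ikr_protocol`.
#' @export
build_pr2 <- function(config = NULL) {
  cfg <- .pr_cfg("Pr2", config)
  d <- cfg$p1_durations
  if (length(d) > 1 && any(diff(d) <= 0))
    stop("Pr2 P1 durations must be strictly increasing")
  sweeps <- lapply(d, function(di) list(
    seg_step(cfg$hold1, cfg$holding, "hold1"),
    seg_step(di, cfg$p1_voltage, "P1"),
    seg_step(cfg$tail, cfg$tail_voltage, "tail"),
    seg_step(cfg$hold2, cfg$holding, "hold2")))
  new_protocol("Pr2", sweeps, cfg$dt)
}

#' @rdname build_pr2
#' @export
build_pr3 <- function(config = NULL) {
  cfg <- .pr_cfg("Pr3", config)
  v <- cfg$p1_voltages
  if (anyDuplicated(v)) stop("Pr3 P1 voltages must be distinct")
  sweeps <- lapply(v, function(vi) list(
    seg_step(cfg$hold1, cfg$holding, "hold1"),
    seg_step(cfg$p1_duration, vi, "P1"),
    seg_step(cfg$tail, cfg$tail_voltage, "tail"),
    seg_step(cfg$hold2, cfg$holding, "hold2")))
  new_protocol("Pr3", sweeps, cfg$dt)
}

#' @rdname build_pr2
#' @export
build_pr4 <- function(config = NULL) {
  cfg <- .pr_cfg("Pr4", config)
  sweeps <- lapply(cfg$p3_voltages, function(vi) list(
    seg_step(cfg$hold1, cfg$holding, "hold1"),
    seg_step(cfg$p1, cfg$p1_voltage, "P1"),
    seg_step(cfg$p2, cfg$p2_voltage, "P2"),
    seg_step(cfg$p3, vi, "P3"),
    seg_step(cfg$hold2, cfg$holding, "hold2")))
  new_protocol("Pr4", sweeps, cfg$dt)
}

#' @rdname build_pr2
#' @export
build_pr5 <- function(config = NULL) {
  cfg <- .pr_cfg("Pr5", config)
  sweeps <- lapply(cfg$p2_voltages, function(vi) list(
    seg_step(cfg$hold1, cfg$holding, "hold1"),
    seg_step(cfg$p1, cfg$p1_voltage, "P1"),
    seg_step(cfg$p2, vi, "P2"),
    seg_step(cfg$hold2, cfg$holding, "hold2")))
  new_protocol("Pr5", sweeps, cfg$dt)
}

#' @rdname build_pr2
#' @export
build_pr7 <- function(config = NULL) {
  cfg <- .pr_cfg("Pr7", config)
  sweeps <- list(list(
    seg_step(cfg$hold1, cfg$holding, "hold1"),
    seg_step(cfg$step, cfg$step_voltage, "step"),
    seg_sine(cfg$sine_duration, cfg$sine_offset, cfg$sine_amplitudes,
             cfg$sine_omegas, cfg$sine_phases, "sine"),
    seg_step(cfg$hold2, cfg$holding, "hold2")))
  new_protocol("Pr7", sweeps, cfg$dt)
}

#' All default fitting protocols
#'
#' @param dt sampling interval in ms (default from the shipped config).
#' @return named list with Pr2, Pr3, Pr4, Pr5 and Pr7.
#' @export
default_protocols <- function(dt = NULL) {
  ov <- if (is.null(dt)) NULL else list(dt = dt)
  list(Pr2 = build_pr2(ov), Pr3 = build_pr3(ov), Pr4 = build_pr4(ov),
       Pr5 = build_pr5(ov), Pr7 = build_pr7(ov))
}

#' Load / write a sampled-waveform protocol (e.g. an AP-clamp file)
#'
#' Two-column whitespace- or comma-delimited text: time (ms, strictly
#' increasing from 0) and voltage (mV). Produces a single-sweep protocol
#' holding one sampled-waveform segment.
#'
#' @param path text file path.
#' @param name protocol name.
#' @param dt sampling interval for simulation output, ms.
#' @export
load_sampled_protocol <- function(path, name = "Pr6", dt = NULL) {
  if (is.null(dt)) dt <- protocol_config()$dt
  tab <- tryCatch(utils::read.table(path, header = FALSE, sep = "",
                                    comment.char = "#"),
                  error = function(e) stop("cannot parse sampled protocol: ",
                                           conditionMessage(e)))
  if (nrow(tab) < 2 || ncol(tab) < 2) stop("sampled protocol needs two columns")
  tms <- as.numeric(tab[[1]]); v <- as.numeric(tab[[2]])
  if (any(!is.finite(tms)) || any(!is.finite(v)))
    stop("non-numeric values in sampled protocol")
  if (any(diff(tms) <= 0)) stop("times must be strictly increasing")
  tms <- tms - tms[1]
  new_protocol(name, list(list(seg_sampled(tms, v, "waveform"))), dt)
}

#' @rdname load_sampled_protocol
#' @param protocol a single-sweep protocol with one sampled segment.
#' @export
write_sampled_protocol <- function(protocol, path) {
  seg <- protocol$sweeps[[1]][[1]]
  stopifnot(seg$kind == "sampled")
  write.table(data.frame(time_ms = sprintf("%.12g", seg$times),
                         voltage_mV = sprintf("%.12g", seg$voltages)),
              path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}

## -------------------------------------------------------------------------
## Capacitance-artifact blanking
## -------------------------------------------------------------------------

sweep_discontinuities <- function(segs) {
  ## sweep start counts as a discontinuity; interior boundaries do when the
  ## left/right voltage limits differ by more than 1e-9 mV
  td <- 0
  ends <- cumsum(vapply(segs, function(s) s$duration, 0))
  if (length(segs) > 1) {
    for (k in seq_len(length(segs) - 1)) {
      vl <- segment_voltage_limits(segs[[k]])[2]
      vr <- segment_voltage_limits(segs[[k + 1]])[1]
      if (abs(vl - vr) > 1e-9) td <- c(td, ends[k])
    }
  }
  td
}

#' Capacitance-artifact mask
#'
#' Flags, per sweep, the samples falling within `window` ms after each
#' discontinuous voltage step (including the sweep start) as FALSE
#' ("discard"). Depends only on the voltage command, so the identical mask
#' applies to measured and simulated traces.
#'
#' @inheritParams sweep_duration
#' @param dt sampling interval, ms.
#' @param window blanking window after each discontinuity, ms.
#' @return list of logical keep-vectors, one per sweep.
#' @export
capacitance_mask <- function(protocol, dt = protocol$dt, window = 5) {
  stopifnot(window >= 0)
  lapply(seq_along(protocol$sweeps), function(i) {
    segs <- protocol$sweeps[[i]]
    n <- round(sweep_duration(protocol, i) / dt)
    tt <- (seq_len(n) - 1) * dt
    keep <- rep(TRUE, n)
    if (window > 0) {
      for (td in sweep_discontinuities(segs))
        keep[tt >= td - 1e-9 & tt < td + window - 1e-9] <- FALSE
    }
    keep
  })
}

#' Sample indices of a labelled segment
#'
#' Returns the (1-based) indices of trace samples belonging to the first
#' segment of a sweep carrying `label`.
#'
#' @inheritParams sweep_duration
#' @param label segment label, e.g. "P1", "tail".
#' @param dt sampling interval, ms.
#' @export
sample_window <- function(protocol, sweep, label, dt = protocol$dt) {
  segs <- protocol$sweeps[[sweep]]
  labs <- vapply(segs, function(s) s$label, "")
  k <- match(label, labs)
  if (is.na(k)) stop("no segment labelled '", label, "' in sweep ", sweep)
  ends <- cumsum(vapply(segs, function(s) s$duration, 0))
  starts <- c(0, ends[-length(ends)])
  i0 <- ceiling(starts[k] / dt - 1e-6)          # first sample index (0-based)
  i1 <- ceiling(ends[k] / dt - 1e-6) - 1        # last sample strictly inside
  seq.int(i0 + 1, i1 + 1)
}
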