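## Synthetic-cell generator: model-generated currents for every protocol
## plus iid Gaussian noise of known standard deviation, with the
## ground-truth parameters attached. This reproduces the package's in
## silico validation design: everything downstream (extraction, all four
## fitting methods, cross-validation) can be exercised against a known
## truth without any external data.

#' Synthetic-cell specification
#'
#' @param params true [ikr_params].
#' @param conditions an [ionic_conditions] object.
#' @param noise_sigma Gaussian noise standard deviation in current units;
#'   when NULL, `noise_frac` of the noiseless Pr7 current range is used
#'   (the default 2% is comparable to the strongest noise seen in typical
#'   whole-cell recordings of this kind).
#' @param noise_frac fraction of the Pr7 range defining the default sigma.
#' @param seed integer seed; the dataset is fully determined by it.
#' @param protocols named list of protocols (Pr2-Pr5, Pr6, Pr7); defaults
#'   to the shipped set plus a generated AP waveform.
#' @export
synthetic_spec <- function(params = NULL, conditions = ionic_conditions(),
                           noise_sigma = NULL, noise_frac = 0.02, seed = 1,
                           protocols = NULL) {
  if (is.null(params))
    params <- default_fixture_params()
  if (is.null(protocols)) {
    protocols <- default_protocols()
    protocols$Pr6 <- generate_ap_waveform(seed = seed)
  }
  structure(list(params = ikr_params(as.numeric(params)),
                 conditions = conditions, noise_sigma = noise_sigma,
                 noise_frac = noise_frac, seed = seed,
                 protocols = protocols),
            class = "ikr_synth_spec")
}

## fixture truth: hERG-like kinetics (activation tau of order seconds at
## moderately negative voltages, inactivation tau of order 10 ms),
## documented defaults for testing -- not asserted as any cell's truth.
default_fixture_params <- function() {
  ikr_params(2.26e-4, 0.0699, 3.45e-5, 0.05462,
             0.0873, 8.91e-3, 5.15e-3, 0.03158, 0.1524)
}

#' Default synthetic-cell fixture
#'
#' The package's documented default: plausible hERG-like truth
#' parameters, E_K near -88 mV, noise at 2% of the noiseless sine-wave
#' protocol current range.
#'
#' @param seed integer seed.
#' @param dt sampling interval, ms (default from the shipped config).
#' @export
default_fixture <- function(seed = 1, dt = NULL) {
  prot <- default_protocols(dt)
  prot$Pr6 <- generate_ap_waveform(seed = seed, dt = dt %||% protocol_config()$dt)
  synthetic_spec(default_fixture_params(), ionic_conditions(),
                 seed = seed, protocols = prot)
}

#' Generate a synthetic cell
#'
#' Simulates every protocol listed in `spec` (analytically for step protocols,
#' by adaptive ODE integration for Pr6/Pr7), adds iid Gaussian noise to
#' the current samples, and derives the summary curves from the noisy
#' traces exactly as for measured data.
#'
#' @param spec a [synthetic_spec].
#' @param id cell identifier.
#' @return a [cell_dataset]; the truth is stored in `$truth` and the noise
#'   sd used in `$noise_sigma`.
#' @export
generate_cell <- function(spec = synthetic_spec(), id = "synthetic-1") {
  prot <- spec$protocols
  cond <- spec$conditions
  clean <- lapply(prot, function(pr)
    simulate_protocol(spec$params, pr, cond))
  sigma <- spec$noise_sigma
  if (is.null(sigma)) {
    rng <- diff(range(clean$Pr7[[1]]$current))
    sigma <- spec$noise_frac * rng
  }
  set.seed(spec$seed)
  noisy <- lapply(clean, function(trs) lapply(trs, function(tr) {
    tr$current <- tr$current + rnorm(nrow(tr), 0, sigma)
    tr
  }))
  summ <- suppressWarnings(
    assemble_summary(noisy[c("Pr2", "Pr3", "Pr4", "Pr5")], prot, cond))
  cell <- cell_dataset(id, noisy, summ, cond, prot)
  cell$truth <- spec$params
  cell$noise_sigma <- sigma
  cell
}

#' Deterministic synthetic action-potential waveform protocol
#'
#' A stand-in for the real AP-clamp recording (which must be downloaded):
#' a train of AP-like waveforms -- resting potential near -80 mV, fast
#' upstroke, dome, repolarization -- of several durations, including one
#' early-afterdepolarization-like morphology. Deterministic given `seed`.
#'
#' @param path optional file path; when given, the waveform is written in
#'   the two-column sampled-protocol format.
#' @param seed integer seed (jitters amplitudes/durations slightly).
#' @param dt simulation sampling interval for the returned protocol, ms.
#' @param node_ms waveform node spacing, ms.
#' @return the `ikr_protocol` (invisibly the path when `path` is given).
#' @export
generate_ap_waveform <- function(path = NULL, seed = 1, dt = NULL,
                                 node_ms = 2) {
  if (is.null(dt)) dt <- protocol_config()$dt
  set.seed(seed)
  rest <- -80
  apd <- c(250, 300, 350, 420, 220)       # ms, per beat
  gap <- c(300, 250, 300, 350, 300)       # rest before each beat
  peak <- 40 + runif(5, -3, 3)
  ead <- c(FALSE, FALSE, FALSE, TRUE, FALSE)
  total <- sum(apd) + sum(gap) + 400
  tt <- seq(0, total, by = node_ms)
  vv <- rep(rest, length(tt))
  t0 <- 0
  for (b in seq_along(apd)) {
    t0 <- t0 + gap[b]
    up <- 2                                # upstroke duration, ms
    ph <- tt - t0
    in_up <- ph >= 0 & ph < up
    vv[in_up] <- rest + (peak[b] - rest) * ph[in_up] / up
    in_ap <- ph >= up & ph < apd[b]
    u <- (ph[in_ap] - up) / (apd[b] - up)
    v_ap <- rest + (peak[b] - rest) * (1 - u)^1.6 * (0.75 + 0.25 * cos(3 * u))
    if (ead[b]) {
      bump <- ifelse(u > 0.5 & u < 0.9,
                     18 * sin(pi * (u - 0.5) / 0.4)^2, 0)
      v_ap <- v_ap + bump
    }
    vv[in_ap] <- v_ap
    t0 <- t0 + apd[b]
  }
  vv <- pmin(60, pmax(-120, vv))
  prot <- new_protocol("Pr6", list(list(seg_sampled(tt, vv, "waveform"))), dt)
  if (!is.null(path)) {
    write_sampled_protocol(prot, path)
    return(invisible(prot))
  }
  prot
}
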