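## Bounded, log-transformed, multi-start CMA-ES optimization of the
## simulation-based error measures.
##
## The feasible region combines box bounds on p1..p9 with constraints on
## the transition rates: each rate, evaluated at the voltage where it is
## largest over the physiological interval (k1, k3 at V_hi; k2, k4 at
## V_lo), must lie in [k_min, k_max]. Because each rate is monotone in V,
## this endpoint check is exact. Proposals outside the region score +Inf.

#' Parameter-space bounds
#'
#' Defaults span ~10 orders of magnitude for the rate pre-factors (which
#' is why they are searched in log space) and cap voltage sensitivities at
#' 0.4 mV^-1; rate bounds keep every transition between ~17 min and 1 us
#' timescales over the physiological voltage range.
#'
#' @param lower,upper length-9 vectors of box bounds for p1..p9.
#' @param k_min,k_max bounds (ms^-1) on each rate's maximum over
#'   `[V_lo, V_hi]`.
#' @param V_lo,V_hi physiological voltage interval, mV.
#' @export
parameter_bounds <- function(lower = c(1e-7, 1e-7, 1e-7, 1e-7,
                                       1e-7, 1e-7, 1e-7, 1e-7, 1e-5),
                             upper = c(1e3, 0.4, 1e3, 0.4,
                                       1e3, 0.4, 1e3, 0.4, 1e3),
                             k_min = 1.67e-5, k_max = 1e3,
                             V_lo = -120, V_hi = 60) {
  stopifnot(length(lower) == 9, length(upper) == 9, all(lower < upper),
            k_min > 0, k_min < k_max, V_lo < V_hi)
  structure(list(lower = lower, upper = upper, k_min = k_min, k_max = k_max,
                 V_lo = V_lo, V_hi = V_hi), class = "ikr_bounds")
}

#' Feasibility check
#'
#' TRUE iff every parameter is inside its box and every maximal rate
#' (endpoint-evaluated; rates are monotone in voltage) lies within
#' `[k_min, k_max]`.
#'
#' @param params numeric vector p1..p9 (not necessarily positive).
#' @param bounds a [parameter_bounds] object.
#' @export
in_bounds <- function(params, bounds = parameter_bounds()) {
  p <- as.numeric(params)
  if (length(p) != 9 || any(!is.finite(p))) return(FALSE)
  if (any(p < bounds$lower) || any(p > bounds$upper)) return(FALSE)
  kmx <- c(p[1] * exp(p[2] * bounds$V_hi),   # k1 largest at V_hi
           p[3] * exp(-p[4] * bounds$V_lo),  # k2 largest at V_lo
           p[5] * exp(p[6] * bounds$V_hi),   # k3 largest at V_hi
           p[7] * exp(-p[8] * bounds$V_lo))  # k4 largest at V_lo
  all(is.finite(kmx)) && all(kmx >= bounds$k_min) && all(kmx <= bounds$k_max)
}

#' Search-space transform
#'
#' Log transform on the rate pre-factors p1, p3, p5, p7 (and by default
#' the conductance p9, which also spans decades); identity elsewhere.
#'
#' @param log_params indices of log-transformed parameters.
#' @export
search_transform <- function(log_params = c(1, 3, 5, 7, 9)) {
  lg <- rep(FALSE, 9); lg[log_params] <- TRUE
  structure(list(log = lg), class = "ikr_transform")
}

#' @rdname search_transform
#' @param params parameter vector (natural space).
#' @param transform an `ikr_transform`.
#' @export
to_search_space <- function(params, transform = search_transform()) {
  x <- as.numeric(params)
  x[transform$log] <- log(x[transform$log])
  x
}

#' @rdname search_transform
#' @param x point in transformed space.
#' @export
from_search_space <- function(x, transform = search_transform()) {
  p <- as.numeric(x)
  p[transform$log] <- exp(p[transform$log])
  names(p) <- paste0("p", 1:9)
  p
}

transformed_box <- function(bounds, transform) {
  list(lower = to_search_space(bounds$lower, transform),
       upper = to_search_space(bounds$upper, transform))
}

#' Sample feasible starting points
#'
#' Uniform in the transformed box, rejection-sampled against the rate
#' constraints; reproducible given `seed`.
#'
#' @param n number of points.
#' @param bounds a [parameter_bounds] object.
#' @param transform an `ikr_transform`.
#' @param seed integer seed.
#' @return matrix (n x 9) of parameter vectors in natural space.
#' @export
sample_start_points <- function(n, bounds = parameter_bounds(),
                                transform = search_transform(), seed = 1) {
  box <- transformed_box(bounds, transform)
  set.seed(seed)
  out <- matrix(NA_real_, n, 9, dimnames = list(NULL, paste0("p", 1:9)))
  got <- 0L; tries <- 0L
  while (got < n) {
    if ((tries <- tries + 1L) > 20000L * n)
      stop("rejection sampling failed; bounds too restrictive")
    x <- box$lower + runif(9) * (box$upper - box$lower)
    p <- from_search_space(x, transform)
    if (in_bounds(p, bounds)) { got <- got + 1L; out[got, ] <- p }
  }
  out
}

#' Physiologically plausible random parameter sets
#'
#' Multiplicative log-normal jitter around the package's fixture
#' parameters, rejected against [in_bounds]. Used for recovery and
#' equivalence tests: uniform draws over the full (10-decade) feasible box
#' routinely produce kinetics no finite protocol can identify, whereas
#' these stay within the identifiable, hERG-like regime.
#'
#' @param n number of parameter sets.
#' @param seed integer seed.
#' @param sdlog standard deviation of the log-normal jitter.
#' @param base centre of the jitter (default: fixture truth).
#' @param bounds feasibility region.
#' @return matrix (n x 9).
#' @export
sample_physiological_params <- function(n, seed = 1, sdlog = log(1.3),
                                        base = default_fixture()$params,
                                        bounds = parameter_bounds()) {
  set.seed(seed)
  out <- matrix(NA_real_, n, 9, dimnames = list(NULL, paste0("p", 1:9)))
  got <- 0L; tries <- 0L
  while (got < n) {
    if ((tries <- tries + 1L) > 10000L * n) stop("sampling failed")
    p <- as.numeric(base) * exp(rnorm(9, 0, sdlog))
    if (in_bounds(p, bounds)) { got <- got + 1L; out[got, ] <- p }
  }
  out
}

#' CMA-ES configuration
#'
#' Defaults follow the package's fitting strategy: population 10, stop
#' when the best objective value changes by less than `ftol` per iteration
#' for `stall_iters` successive iterations; `max_iters` is a runtime
#' guard. `sigma_frac` sets the initial per-coordinate step size as a
#' fraction of the transformed bound width.
#'
#' @param pop_size CMA-ES population size (lambda).
#' @param ftol stall detection threshold on the best objective value.
#' @param stall_iters successive quiet iterations required to stop.
#' @param max_iters hard iteration cap.
#' @param sigma_frac initial step size as fraction of bound width.
#' @export
cmaes_config <- function(pop_size = 10, ftol = 1e-11, stall_iters = 200,
                         max_iters = 2000, sigma_frac = 1 / 6) {
  list(pop_size = pop_size, ftol = ftol, stall_iters = stall_iters,
       max_iters = max_iters, sigma_frac = sigma_frac)
}

## Standard (mu/mu_w, lambda) CMA-ES with rank-mu update (Hansen's
## tutorial formulation). Minimizes fn over R^n; fn may return Inf.
cmaes_minimize <- function(fn, x0, scale, config) {
  n <- length(x0)
  lambda <- config$pop_size
  mu <- floor(lambda / 2)
  w <- log(mu + 0.5) - log(seq_len(mu))
  w <- w / sum(w)
  mueff <- 1 / sum(w^2)
  cc <- (4 + mueff / n) / (n + 4 + 2 * mueff / n)
  cs <- (mueff + 2) / (n + mueff + 5)
  c1 <- 2 / ((n + 1.3)^2 + mueff)
  cmu <- min(1 - c1, 2 * (mueff - 2 + 1 / mueff) / ((n + 2)^2 + mueff))
  damps <- 1 + 2 * max(0, sqrt((mueff - 1) / (n + 1)) - 1) + cs
  chiN <- sqrt(n) * (1 - 1 / (4 * n) + 1 / (21 * n^2))

  xmean <- x0
  sigma <- 1
  C <- diag(scale^2, n)
  ps <- pc <- numeric(n)
  B <- diag(n); D <- scale
  ## the starting point itself is evaluated so a fit can never end worse
  ## than where it began (relevant for seeded starts)
  best_x <- x0; best_f <- fn(x0)
  evals <- 1L
  prev_best <- Inf; stall <- 0L; converged <- FALSE
  iters <- 0L

  for (iter in seq_len(config$max_iters)) {
    iters <- iter
    Z <- matrix(rnorm(n * lambda), n, lambda)
    Y <- B %*% (D * Z)                      # N(0, C) samples
    X <- xmean + sigma * Y
    f <- numeric(lambda)
    for (k in seq_len(lambda)) f[k] <- fn(X[, k])
    evals <- evals + lambda
    ord <- order(f)
    if (f[ord[1]] < best_f) { best_f <- f[ord[1]]; best_x <- X[, ord[1]] }

    sel <- ord[seq_len(mu)]
    ymean <- drop(Y[, sel, drop = FALSE] %*% w)
    xmean <- xmean + sigma * ymean

    ## evolution paths
    Cinv_half_y <- B %*% ((1 / D) * crossprod(B, ymean))
    ps <- (1 - cs) * ps + sqrt(cs * (2 - cs) * mueff) * drop(Cinv_half_y)
    hsig <- sqrt(sum(ps^2)) / sqrt(1 - (1 - cs)^(2 * iter)) / chiN <
      1.4 + 2 / (n + 1)
    pc <- (1 - cc) * pc + hsig * sqrt(cc * (2 - cc) * mueff) * ymean

    ## covariance update
    Ysel <- Y[, sel, drop = FALSE]
    C <- (1 - c1 - cmu) * C +
      c1 * (tcrossprod(pc) + (1 - hsig) * cc * (2 - cc) * C) +
      cmu * Ysel %*% (w * t(Ysel))
    sigma <- sigma * exp((cs / damps) * (sqrt(sum(ps^2)) / chiN - 1))

    eg <- eigen(C, symmetric = TRUE)
    D <- sqrt(pmax(eg$values, 1e-300))
    B <- eg$vectors

    ## stall-based stopping on the per-iteration best objective value:
    ## while the population still fluctuates the iteration best moves by
    ## far more than ftol, so exploration phases are not cut short
    iter_best <- f[ord[1]]
    ch <- abs(prev_best - iter_best)
    stall <- if (is.finite(iter_best) && is.finite(ch) && ch < config$ftol)
      stall + 1L else 0L
    prev_best <- iter_best
    if (stall >= config$stall_iters) { converged <- TRUE; break }
    if (sigma * max(D) < 1e-12 * max(scale)) { converged <- TRUE; break }
  }
  list(par = best_x, value = best_f, evals = evals, iters = iters,
       converged = converged)
}

#' Run one bounded CMA-ES fit
#'
#' Optimizes `objective` in the transformed space; proposals outside the
#' feasible region score +Inf. Deterministic given `seed` (which also
#' draws the starting point when `start` is NULL).
#'
#' @param objective function(params) -> scalar (Inf allowed).
#' @param bounds a [parameter_bounds] object.
#' @param transform an `ikr_transform`.
#' @param config a [cmaes_config] list.
#' @param seed integer seed.
#' @param start optional starting parameter vector (natural space).
#' @param method label stored in the result.
#' @return an `ikr_fit` list: params, score, method, seed, start, evals,
#'   iters, converged.
#' @export
run_fit <- function(objective, bounds = parameter_bounds(),
                    transform = search_transform(),
                    config = cmaes_config(), seed = 1, start = NULL,
                    method = NA) {
  set.seed(seed)
  if (is.null(start))
    start <- drop(sample_start_points(1, bounds, transform,
                                      seed = seed + 607L))
  if (!in_bounds(start, bounds)) stop("start point out of bounds")
  box <- transformed_box(bounds, transform)
  wrapped <- function(x) {
    p <- from_search_space(x, transform)
    if (!in_bounds(p, bounds)) return(Inf)
    objective(p)
  }
  res <- cmaes_minimize(wrapped, to_search_space(start, transform),
                        scale = config$sigma_frac * (box$upper - box$lower),
                        config = config)
  params <- from_search_space(res$par, transform)
  ok <- is.finite(res$value)
  structure(list(params = if (ok) ikr_params(params) else params,
                 score = res$value, method = method, seed = seed,
                 start = start, evals = res$evals, iters = res$iters,
                 converged = res$converged && ok),
            class = "ikr_fit")
}

#' @export
print.ikr_fit <- function(x, ...) {
  cat(sprintf("Fit (method %s, seed %s): score %.6g after %d evals%s\n",
              x$method, x$seed, x$score, x$evals,
              if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Multi-start fitting
#'
#' Independent seeded repeats from random feasible starting points; the
#' best (lowest-score) repeat is the final fit, ties broken by repeat
#' index.
#'
#' @inheritParams run_fit
#' @param n_repeats number of repeats.
#' @param starts optional matrix of starting points (rows).
#' @param polish_config optional [cmaes_config] for a final local polish:
#'   after the best repeat is selected, one further CMA-ES run is started
#'   from it (use a small `sigma_frac`). The polished result replaces
#'   `best` only if it improves the score; useful when the per-repeat
#'   budget is capped well below full convergence.
#' @return list with `results` (all repeats), `best`, `best_index`.
#' @export
multi_start <- function(objective, n_repeats, bounds = parameter_bounds(),
                        transform = search_transform(),
                        config = cmaes_config(), seed = 1, starts = NULL,
                        method = NA, polish_config = NULL) {
  results <- lapply(seq_len(n_repeats), function(i) {
    run_fit(objective, bounds, transform, config, seed = seed + i,
            start = if (is.null(starts)) NULL else drop(starts[i, ]),
            method = method)
  })
  scores <- vapply(results, function(r) r$score, 0)
  bi <- which.min(scores)
  best <- results[[bi]]
  if (!is.null(polish_config) && is.finite(best$score)) {
    pol <- run_fit(objective, bounds, transform, polish_config,
                   seed = seed + n_repeats + 1L,
                   start = as.numeric(best$params), method = method)
    if (pol$score < best$score) best <- pol
  }
  list(results = results, best = best, best_index = bi)
}

#' Repeat-to-repeat reliability of a multi-start fit
#'
#' Fraction of repeats whose score lies within `rmse_tol` (relative) of
#' the best score, and the fraction that is additionally close in
#' parameter space (no single parameter deviating more than `param_tol`
#' relative from the best fit's value).
#'
#' @param results list of `ikr_fit` (e.g. `multi_start(...)$results`).
#' @param rmse_tol,param_tol relative tolerances (default 1%).
#' @return list: frac_rmse_close, frac_param_close, n.
#' @export
reliability <- function(results, rmse_tol = 0.01, param_tol = 0.01) {
  scores <- vapply(results, function(r) r$score, 0)
  bi <- which.min(scores)
  best <- scores[bi]
  close <- if (best == 0) scores == 0 else scores <= best * (1 + rmse_tol)
  bp <- as.numeric(results[[bi]]$params)
  pclose <- vapply(results, function(r) {
    all(abs(as.numeric(r$params) - bp) <= param_tol * abs(bp))
  }, TRUE) & close
  list(frac_rmse_close = mean(close), frac_param_close = mean(pclose),
       n = length(results))
}

#' Method-1-seeded starting point
#'
#' Projects a method-1 parameter estimate onto the feasible region:
#' componentwise clipping into the (transformed) box, then, if a maximal
#' rate still violates its bound, the corresponding pre-factor is scaled
#' to the nearest feasible value.
#'
#' @param params parameter vector (e.g. from [method1_fit]).
#' @param bounds a [parameter_bounds] object.
#' @param transform an `ikr_transform`.
#' @export
seeded_start_from_method1 <- function(params, bounds = parameter_bounds(),
                                      transform = search_transform()) {
  box <- transformed_box(bounds, transform)
  x <- pmin(box$upper, pmax(box$lower, to_search_space(params, transform)))
  p <- from_search_space(x, transform)
  ## rate-constraint repair on the pre-factors
  vmax <- c(bounds$V_hi, NA, bounds$V_lo, NA, bounds$V_hi, NA, bounds$V_lo, NA)
  sgn <- c(1, NA, -1, NA, 1, NA, -1, NA)
  for (i in c(1, 3, 5, 7)) {
    e <- exp(sgn[i] * p[i + 1] * vmax[i])
    p[i] <- min(max(p[i], bounds$k_min / e * (1 + 1e-12)),
                bounds$k_max / e * (1 - 1e-12))
    p[i] <- min(max(p[i], bounds$lower[i]), bounds$upper[i])
  }
  if (!in_bounds(p, bounds))
    stop("could not project method-1 estimate into bounds")
  stats::setNames(p, paste0("p", 1:9))
}
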