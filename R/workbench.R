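## Evaluation harness: fit all four methods to a cell, validate on the AP
## protocol, build relative-RMSE cross-validation tables and reliability
## summaries.

#' Cross-validation table for one cell
#'
#' Evaluates E_AP, E_M1, E_M2, E_M3 and E_M4 for each method's fitted
#' parameters and scales every row by its minimum, so the best-performing
#' method per criterion reads 1.
#'
#' @param cell a [cell_dataset].
#' @param fits named list of parameter vectors, e.g.
#'   `list(method1 = ..., method2 = ...)`.
#' @return list with `raw` and `relative` matrices (criteria x methods).
#' @export
cross_validate <- function(cell, fits) {
  stopifnot(length(fits) >= 1)
  has_ap <- !is.null(cell$traces$Pr6)
  crits <- c(if (has_ap) "E_AP", "E_M1", "E_M2", "E_M3", "E_M4")
  raw <- matrix(Inf, length(crits), length(fits),
                dimnames = list(crits, names(fits)))
  for (j in seq_along(fits)) {
    p <- fits[[j]]
    ev <- function(f) tryCatch(f, error = function(e) Inf)
    if (has_ap) raw["E_AP", j] <- ev(e_ap(p, cell))
    raw["E_M1", j] <- ev(e_m1(p, cell))
    raw["E_M2", j] <- ev(e_m2(p, cell))
    raw["E_M3", j] <- ev(e_m3(p, cell))
    raw["E_M4", j] <- ev(e_m4(p, cell))
  }
  rmin <- apply(raw, 1, min)
  rel <- raw / rmin
  # a zero row minimum (exact fit on noiseless data) would give 0/0 for
  # the winner; it is the best method, so its relative score is 1
  rel[raw == rmin] <- 1
  list(raw = raw, relative = rel)
}

#' Aggregate cross-validation tables over cells
#'
#' Element-wise mean and standard deviation of the relative tables.
#'
#' @param tables list of [cross_validate] results (or matrices).
#' @export
aggregate_cells <- function(tables) {
  mats <- lapply(tables, function(t) if (is.list(t)) t$relative else t)
  arr <- simplify2array(mats)
  if (length(dim(arr)) == 2) dim(arr) <- c(dim(arr), 1)
  sdm <- apply(arr, c(1, 2), stats::sd)
  if (dim(arr)[3] == 1) sdm[] <- 0   # sd over a single cell reports 0
  dimnames(sdm) <- dimnames(mats[[1]])
  m <- apply(arr, c(1, 2), mean)
  dimnames(m) <- dimnames(mats[[1]])
  list(mean = m, sd = sdm)
}

## deterministic per-(cell, method, repeat-block) seed derivation; keeps
## derived seeds well below 2^31 so any single repeat is re-runnable
study_seed <- function(master, cell_idx, method) {
  (master * 1009L + cell_idx * 101L + method * 13L) %% 1000000000L
}

#' Run the full fitting study on a set of cells
#'
#' For each cell: extract/reuse summary curves, run method 1
#' (deterministic), fit methods 2-4 by multi-start CMA-ES, evaluate the
#' cross-validation table and per-method reliability. Per-cell failures
#' are isolated and reported; the study continues.
#'
#' @param cells list of [cell_dataset]s.
#' @param methods integer subset of 1:4.
#' @param repeats named list of repeat counts (defaults
#'   `list(m2 = 80, m3 = 50, m4 = 50)`).
#' @param repeats_scale multiplier applied (and rounded, min 1) to the
#'   repeat counts -- the knob for desk-scale runs.
#' @param config a [cmaes_config].
#' @param bounds,transform search space definition.
#' @param seed master seed; per-cell/method seeds are derived from it.
#' @return an `ikr_study` list: per-cell fits, tables, reliability, and
#'   the aggregate table.
#' @export
run_study <- function(cells, methods = 1:4,
                      repeats = list(m2 = 80, m3 = 50, m4 = 50),
                      repeats_scale = 1, config = cmaes_config(),
                      bounds = parameter_bounds(),
                      transform = search_transform(), seed = 1) {
  nrep <- function(m) max(1L, round(repeats[[paste0("m", m)]] * repeats_scale))
  per_cell <- lapply(seq_along(cells), function(ci) {
    cell <- cells[[ci]]
    out <- tryCatch({
      fits <- list(); rel <- list(); allres <- list()
      if (1 %in% methods)
        fits$method1 <- method1_fit(cell$summary, cell$protocols$Pr5,
                                    cell$conditions)
      for (m in intersect(2:4, methods)) {
        ms <- multi_start(make_objective(cell, m), nrep(m), bounds,
                          transform, config,
                          seed = study_seed(seed, ci, m), method = m)
        fits[[paste0("method", m)]] <- ms$best$params
        rel[[paste0("method", m)]] <- reliability(ms$results)
        allres[[paste0("method", m)]] <- ms$results
      }
      list(id = cell$id, fits = fits, table = cross_validate(cell, fits),
           reliability = rel, results = allres, error = NULL)
    }, error = function(e) list(id = cell$id, error = conditionMessage(e)))
    out
  })
  ok <- !vapply(per_cell, function(x) !is.null(x$error), TRUE)
  agg <- if (any(ok))
    aggregate_cells(lapply(per_cell[ok], function(x) x$table)) else NULL
  structure(list(cells = per_cell, aggregate = agg, seed = seed,
                 methods = methods), class = "ikr_study")
}

#' @export
print.ikr_study <- function(x, ...) {
  cat(sprintf("Study over %d cell(s), methods %s\n", length(x$cells),
              paste(x$methods, collapse = ",")))
  if (!is.null(x$aggregate)) {
    cat("Mean relative error (rows scaled to best = 1):\n")
    print(round(x$aggregate$mean, 3))
  }
  for (c in x$cells)
    if (!is.null(c$error)) cat("cell", c$id, "FAILED:", c$error, "\n")
  invisible(x)
}

#' 2-D objective landscape scan
#'
#' Grid evaluation of an objective over two parameters around a centre
#' point, holding the others fixed (the tool behind objective-surface
#' exploration; failures/out-of-bounds map to Inf).
#'
#' @param objective function(params) -> scalar.
#' @param centre parameter vector at the centre.
#' @param i,j parameter indices to vary.
#' @param span multiplicative half-range (log10 units for log-scale
#'   parameters, absolute fraction otherwise).
#' @param n grid resolution per axis.
#' @param transform an `ikr_transform` deciding the scan scale.
#' @export
scan_objective <- function(objective, centre, i, j, span = 0.5, n = 11,
                           transform = search_transform()) {
  centre <- as.numeric(centre)
  ax <- function(k) {
    if (transform$log[k])
      exp(seq(log(centre[k]) - span * log(10),
              log(centre[k]) + span * log(10), length.out = n))
    else seq(centre[k] * (1 - span), centre[k] * (1 + span), length.out = n)
  }
  xi <- ax(i); xj <- ax(j)
  z <- matrix(NA_real_, n, n)
  for (a in seq_len(n)) for (b in seq_len(n)) {
    p <- centre; p[i] <- xi[a]; p[j] <- xj[b]
    z[a, b] <- tryCatch(objective(stats::setNames(p, paste0("p", 1:9))),
                        error = function(e) Inf)
  }
  list(x = xi, y = xj, z = z, i = i, j = j)
}
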