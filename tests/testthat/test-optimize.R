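test_that("feasibility check combines box and maximal-rate constraints", {
  b <- parameter_bounds()
  expect_true(in_bounds(fx_params(), b))
  p <- as.numeric(fx_params())
  p1 <- p; p1[1] <- 2e3                      # above its box bound
  expect_false(in_bounds(p1, b))
  # inside every box but with k1 at V_hi above k_max
  p2 <- p; p2[1] <- 900; p2[2] <- 0.3
  expect_true(all(p2 >= b$lower & p2 <= b$upper))
  expect_false(in_bounds(p2, b))
  # dense-grid oracle: feasible iff all rates stay inside their band
  # wherever they peak on the voltage grid
  set.seed(30)
  for (rep in 1:20) {
    pr <- exp(runif(9, log(1e-6), log(1))) * c(1, 0.05, 1, 0.05, 1, 0.05,
                                               1, 0.05, 1)
    V <- seq(b$V_lo, b$V_hi, by = 0.5)
    k <- cbind(pr[1] * exp(pr[2] * V), pr[3] * exp(-pr[4] * V),
               pr[5] * exp(pr[6] * V), pr[7] * exp(-pr[8] * V))
    oracle <- all(pr >= b$lower & pr <= b$upper) &&
      all(apply(k, 2, max) >= b$k_min) && all(apply(k, 2, max) <= b$k_max)
    expect_equal(in_bounds(pr, b), oracle)
  }
})

test_that("search transforms are exact inverse pairs", {
  tr <- search_transform()
  p <- as.numeric(fx_params())
  expect_equal(unname(from_search_space(to_search_space(p, tr), tr)), p,
               tolerance = 1e-15)
  id <- search_transform(integer(0))
  expect_equal(to_search_space(p, id), p)
  # log-space midpoint of the box maps to the geometric mean of the bounds
  b <- parameter_bounds()
  box <- ikrfit:::transformed_box(b, tr)
  mid <- from_search_space((box$lower + box$upper) / 2, tr)
  expect_equal(unname(mid[1]), sqrt(b$lower[1] * b$upper[1]),
               tolerance = 1e-12)
  expect_equal(unname(mid[2]), (b$lower[2] + b$upper[2]) / 2,
               tolerance = 1e-12)
})

test_that("start-point sampling is feasible, seeded and uniform", {
  b <- parameter_bounds()
  x1 <- sample_start_points(20, b, seed = 5)
  x2 <- sample_start_points(20, b, seed = 5)
  expect_identical(x1, x2)
  expect_true(all(apply(x1, 1, in_bounds, bounds = b)))
  # with the rate constraints relaxed the transformed marginals are
  # uniform (the constraints couple p1 and p2, so under the default
  # bounds the marginal is deliberately non-uniform)
  brelax <- parameter_bounds(k_min = 1e-300, k_max = 1e300)
  xs <- sample_start_points(4000, brelax, seed = 6)
  ks <- stats::ks.test(log(xs[, 1]), "punif",
                       log(b$lower[1]), log(b$upper[1]))
  expect_gt(ks$p.value, 0.01)
  ks2 <- stats::ks.test(xs[, 2], "punif", b$lower[2], b$upper[2])
  expect_gt(ks2$p.value, 0.01)
})

test_that("CMA-ES solves a bounded convex problem to high accuracy", {
  set.seed(1)
  target <- runif(9, -0.5, 0.5)
  fn <- function(x) sum((x - target)^2)
  res <- ikrfit:::cmaes_minimize(fn, x0 = rep(0, 9), scale = rep(0.3, 9),
                                 config = cmaes_config(max_iters = 1200))
  expect_lt(sqrt(fn(res$par)), 1e-6)
  expect_true(res$converged)
})

test_that("run_fit is deterministic given a seed", {
  cell <- fx_cell_noisy()
  obj <- make_objective(cell, 1)   # summary objective: cheap
  cfg <- cmaes_config(max_iters = 60)
  f1 <- run_fit(obj, config = cfg, seed = 11, method = 1)
  f2 <- run_fit(obj, config = cfg, seed = 11, method = 1)
  expect_identical(f1$score, f2$score)
  expect_identical(as.numeric(f1$params), as.numeric(f2$params))
  expect_identical(f1$start, f2$start)
  expect_true(in_bounds(f1$params))
})

test_that("multi_start returns the lowest-score repeat as best", {
  cell <- fx_cell_noisy()
  obj <- make_objective(cell, 1)
  ms <- multi_start(obj, 4, config = cmaes_config(max_iters = 40), seed = 3)
  scores <- vapply(ms$results, function(r) r$score, 0)
  expect_equal(ms$best$score, min(scores))
  expect_equal(ms$best_index, which.min(scores))
  one <- multi_start(obj, 1, config = cmaes_config(max_iters = 40), seed = 3)
  expect_equal(one$best_index, 1)
})

test_that("reliability reproduces hand-computed fractions exactly", {
  mk <- function(score, params) structure(
    list(params = params, score = score), class = "ikr_fit")
  base <- as.numeric(fx_params())
  res <- list(mk(1.000, base),
              mk(1.005, base * 1.001),     # close in both senses
              mk(1.005, base * 1.5),       # close in RMSE only
              mk(2.000, base))             # far in RMSE
  r <- reliability(res)
  expect_equal(r$frac_rmse_close, 3 / 4)
  expect_equal(r$frac_param_close, 2 / 4)
  expect_equal(r$n, 4)
  # identical results
  same <- list(mk(0.5, base), mk(0.5, base))
  expect_equal(reliability(same)[1:2],
               list(frac_rmse_close = 1, frac_param_close = 1))
  # nesting holds by construction
  expect_lte(r$frac_param_close, r$frac_rmse_close)
})

test_that("method-1 seeding projects estimates into the feasible region", {
  b <- parameter_bounds()
  p <- as.numeric(fx_params())
  expect_equal(unname(seeded_start_from_method1(p, b)), p,
               tolerance = 1e-12)
  pbad <- p; pbad[1] <- 5e3                  # above the box
  proj <- seeded_start_from_method1(pbad, b)
  expect_true(in_bounds(proj, b))
  expect_equal(unname(proj[-1]), p[-1], tolerance = 1e-9)
})
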