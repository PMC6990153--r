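test_that("Boltzmann fits are exact on exact data and sane on noisy data", {
  v <- seq(-60, 60, by = 20)
  y <- 1 / (1 + exp(0.05 * (-20 - v)))
  fit <- fit_boltzmann(data.frame(voltage = v, value = y), "increasing")
  expect_equal(fit$h, -20, tolerance = 1e-8)
  expect_equal(fit$s, 0.05, tolerance = 1e-8)
  # the fitted curve passes through 0.5 at its midpoint by definition
  expect_equal(1 / (1 + exp(fit$s * (fit$h - fit$h))), 0.5)
  # decreasing direction
  yr <- 1 / (1 + exp(-0.04 * (-55 - v)))
  fr <- fit_boltzmann(data.frame(voltage = v, value = yr), "decreasing")
  expect_equal(fr$h, -55, tolerance = 1e-8)
  expect_equal(fr$s, -0.04, tolerance = 1e-8)
  expect_error(fit_boltzmann(data.frame(voltage = v, value = rep(1, 7))),
               "degenerate")

  # recovery under noise, cross-checked against a dense 2-D grid search
  set.seed(9)
  yn <- pmin(1, pmax(0, y + rnorm(7, 0, 0.02)))
  fn <- fit_boltzmann(data.frame(voltage = v, value = yn), "increasing")
  hs <- seq(-30, -10, length.out = 161)
  ss <- seq(0.02, 0.09, length.out = 141)
  sse <- outer(hs, ss, Vectorize(function(h, s)
    sum((1 / (1 + exp(s * (h - v))) - yn)^2)))
  best <- arrayInd(which.min(sse), dim(sse))
  expect_lt(abs(fn$h - hs[best[1]]), diff(hs[1:2]) + 1e-9)
  expect_lt(abs(fn$s - ss[best[2]]), diff(ss[1:2]) + 1e-9)
})

test_that("rate back-substitution is exact on analytic summary curves", {
  mats <- sample_physiological_params(3, seed = 10)
  for (i in 1:3) {
    p <- ikr_params(mats[i, ])
    s <- fx_analytic_summary(p)
    ba <- fit_boltzmann(s$act_ss, "increasing")
    act <- activation_rates_from_summary(ba, s$tau_act)
    expect_equal(unname(act), as.numeric(p)[1:4], tolerance = 1e-6)
    # the Boltzmann slope equals p2 + p4 identically
    expect_equal(ba$s, unname(act["p2"] + act["p4"]), tolerance = 1e-9)
    br <- fit_boltzmann(s$inact_ss, "decreasing")
    inact <- inactivation_rates_from_summary(br, s$tau_inact)
    expect_equal(unname(inact), as.numeric(p)[5:8], tolerance = 1e-6)
    expect_equal(-br$s, unname(inact["p6"] + inact["p8"]), tolerance = 1e-9)
  }
})

test_that("rate regressions track a weighted-LS oracle under noise", {
  p <- fx_params()
  s <- fx_analytic_summary(p)
  set.seed(12)
  s$tau_act$value <- s$tau_act$value * (1 + rnorm(9, 0, 0.01))
  ba <- fit_boltzmann(s$act_ss, "increasing")
  act <- activation_rates_from_summary(ba, s$tau_act)
  # oracle: the same log-linear regression done longhand
  a_inf <- 1 / (1 + exp(ba$s * (ba$h - s$tau_act$voltage)))
  co <- coef(lm(log(a_inf / s$tau_act$value) ~ s$tau_act$voltage))
  expect_equal(unname(act["p1"]), exp(unname(co[1])), tolerance = 1e-10)
  expect_equal(unname(act["p2"]), unname(co[2]), tolerance = 1e-10)
})

test_that("conductance scaling has the closed-form optimum", {
  p <- fx_params()
  cell <- fx_cell_noiseless()
  pr5 <- cell$protocols$Pr5
  s <- fx_analytic_summary(p)
  # proportional IV data returns the true conductance almost exactly
  g <- conductance_from_iv(as.numeric(p)[1:8], s$iv, pr5)
  expect_equal(g, p[["p9"]], tolerance = 1e-8)
  iv2 <- s$iv; iv2$value <- 2 * iv2$value
  expect_equal(conductance_from_iv(as.numeric(p)[1:8], iv2, pr5),
               2 * p[["p9"]], tolerance = 1e-8)
  # closed form equals a 1-D numeric minimization of the SSE
  set.seed(13)
  ivn <- s$iv; ivn$value <- ivn$value * (1 + rnorm(9, 0, 0.05))
  gn <- conductance_from_iv(as.numeric(p)[1:8], ivn, pr5)
  unit <- ikrfit:::analyse_pr5_iv(
    simulate_step(ikr_params(c(as.numeric(p)[1:8], 1)), pr5), pr5)
  sse <- function(g) sum((g * unit$value[match(ivn$voltage, unit$voltage)] -
                            ivn$value)^2)
  gg <- optimize(sse, c(1e-4, 10), tol = 1e-12)$minimum
  expect_equal(gn, gg, tolerance = 1e-6)
})

test_that("the full direct fit is deterministic and exact on exact input", {
  p <- fx_params()
  cell <- fx_cell_noiseless()
  s <- fx_analytic_summary(p)
  m1a <- method1_fit(s, cell$protocols$Pr5)
  m1b <- method1_fit(s, cell$protocols$Pr5)
  expect_identical(m1a, m1b)
  expect_lt(max(abs(as.numeric(m1a)[1:8] / as.numeric(p)[1:8] - 1)), 1e-6)
  expect_lt(abs(m1a[[9]] / p[[9]] - 1), 1e-6)
})

test_that("numerical method-1 beats the direct fit on its own objective", {
  cell <- fx_cell_noisy()
  m1 <- method1_fit(cell$summary, cell$protocols$Pr5, cell$conditions)
  m1n <- method1_numeric(cell$summary, cell$protocols$Pr5, cell$conditions,
                         config = cmaes_config(max_iters = 400), seed = 7,
                         start = seeded_start_from_method1(m1))
  expect_lte(e_m1(m1n, cell), e_m1(m1, cell) + 1e-12)
  # E_M1 ignores the conductance of the start point entirely
  m1p <- as.numeric(m1); m1p[9] <- m1p[9] * 50
  expect_equal(e_m1(ikr_params(m1p), cell), e_m1(m1, cell))
})
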