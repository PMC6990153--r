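test_that("fit_exponential recovers exact signals and flags flat ones", {
  tt <- seq(0, 100, by = 0.1)
  fit <- fit_exponential(tt, 2 * exp(-tt / 15) + 1)
  expect_equal(fit$tau, 15, tolerance = 1e-7)
  expect_equal(fit$amplitude, 2, tolerance = 1e-6)
  expect_equal(fit$offset, 1, tolerance = 1e-6)
  # constant data -> no-fit sentinel with warning
  expect_warning(res <- fit_exponential(tt, rep(3, length(tt))), "floor")
  expect_null(res)
  # two well-separated phases recovered within 0.1%
  y2 <- 1.5 * exp(-tt / 5) - 0.8 * exp(-tt / 50) + 0.2
  f2 <- fit_exponential(tt, y2, n_phases = 2)
  expect_equal(f2$fast$tau, 5, tolerance = 1e-3)
  expect_equal(f2$slow$tau, 50, tolerance = 1e-3)
  expect_error(fit_exponential(1:4, 1:4), "5 samples")
})

test_that("noiseless extraction yields the documented point counts", {
  cell <- fx_cell_noiseless()
  s <- cell$summary
  expect_equal(nrow(s$act_ss), 7)
  expect_equal(nrow(s$inact_ss), 8)
  expect_equal(nrow(s$tau_act), 9)
  expect_equal(nrow(s$tau_inact), 17)
  expect_equal(nrow(s$iv), 9)
  # single +40 mV activation point from Pr2
  expect_equal(sum(s$tau_act$voltage == 40), 1)
  # no inactivation taus below -40 mV come from Pr4 (they are Pr5's)
  expect_true(all(s$tau_inact$value > 0))
  expect_true(all(s$act_ss$value >= 0 & s$act_ss$value <= 1))
  expect_true(all(s$inact_ss$value >= 0 & s$inact_ss$value <= 1))
})

test_that("extracted curves approximate the model variables", {
  # bounded-discrepancy checks: on this model the summary curves are
  # approximations by construction (peak-based steady states are biased
  # where deactivation competes with recovery), so equality is not the
  # right oracle
  cell <- fx_cell_noiseless()
  p <- cell$truth
  s <- cell$summary
  g_ta <- gate_summary(p, s$tau_act$voltage)$tau_a
  expect_lt(max(abs(s$tau_act$value - g_ta) / g_ta), 0.05)
  g_tr <- gate_summary(p, s$tau_inact$voltage)$tau_r
  expect_lt(max(abs(s$tau_inact$value - g_tr) / g_tr), 0.15)
  # activation curve: monotone, approaching 1 at the top
  expect_true(all(diff(s$act_ss$value) >= -1e-10))
  expect_gt(s$act_ss$value[nrow(s$act_ss)], 0.99)
  # inactivation steady state: decreasing over its negative-voltage branch
  # and within 0.25 of the model curve (peak-derived values are biased
  # high after normalization at strongly negative voltages)
  g_r <- gate_summary(p, s$inact_ss$voltage)$r_inf
  expect_lt(max(abs(s$inact_ss$value - g_r)), 0.25)
  # decreasing over the negative branch, modulo the small peak-detection
  # wobble near saturation
  neg <- s$inact_ss$voltage < 0
  expect_true(all(diff(s$inact_ss$value[neg]) <= 0.02))
  expect_gt(s$inact_ss$value[1] - s$inact_ss$value[sum(neg)], 0.3)
})

test_that("summary extraction is scale invariant except for the IV curve", {
  cell <- fx_cell_noiseless()
  scaled <- cell
  for (nm in c("Pr2", "Pr3", "Pr4", "Pr5"))
    scaled$traces[[nm]] <- lapply(cell$traces[[nm]], function(tr) {
      tr$current <- tr$current * 3.7
      tr
    })
  s1 <- cell$summary
  s2 <- suppressWarnings(assemble_summary(
    scaled$traces[c("Pr2", "Pr3", "Pr4", "Pr5")], cell$protocols,
    cell$conditions))
  expect_equal(s2$act_ss$value, s1$act_ss$value, tolerance = 1e-9)
  expect_equal(s2$inact_ss$value, s1$inact_ss$value, tolerance = 1e-9)
  expect_equal(s2$tau_act$value, s1$tau_act$value, tolerance = 1e-6)
  expect_equal(s2$tau_inact$value, s1$tau_inact$value, tolerance = 1e-6)
  expect_equal(s2$iv$value, 3.7 * s1$iv$value, tolerance = 1e-9)
})

test_that("extraction only sees mask-retained samples", {
  cell <- fx_cell_noiseless()
  corrupted <- lapply(names(cell$traces[c("Pr2", "Pr3", "Pr4", "Pr5")]),
    function(nm) lapply(cell$traces[[nm]], function(tr) {
      bad <- !attr(tr, "mask")
      tr$current[bad] <- 1e6     # capacitance-spike-like garbage
      tr
    }))
  names(corrupted) <- c("Pr2", "Pr3", "Pr4", "Pr5")
  s2 <- suppressWarnings(assemble_summary(corrupted, cell$protocols,
                                          cell$conditions))
  expect_equal(s2$act_ss$value, cell$summary$act_ss$value)
  expect_equal(s2$tau_inact$value, cell$summary$tau_inact$value)
  expect_equal(s2$iv$value, cell$summary$iv$value)
})

test_that("Pr2 envelope analysis returns a single scale-invariant point", {
  cell <- fx_cell_noiseless()
  pr2 <- cell$protocols$Pr2
  pt <- tau_act_from_pr2(cell$traces$Pr2, pr2)
  expect_equal(nrow(pt), 1)
  expect_equal(pt$voltage, 40)
  tau_true <- gate_summary(cell$truth, 40)$tau_a
  expect_lt(abs(pt$value - tau_true) / tau_true, 0.05)
  # conductance scaling leaves the envelope tau unchanged
  scaled <- lapply(cell$traces$Pr2, function(tr) {
    tr$current <- tr$current * 0.21
    tr
  })
  expect_equal(tau_act_from_pr2(scaled, pr2)$value, pt$value,
               tolerance = 1e-9)
  # too few usable peaks -> sentinel
  expect_warning(out <- tau_act_from_pr2(cell$traces$Pr2[1:3], pr2),
                 "fewer than 4")
  expect_null(out)
})

test_that("summary CSV round-trips", {
  cell <- fx_cell_noiseless()
  f <- tempfile(fileext = ".csv")
  write_summary(cell$summary, f)
  back <- read_summary(f)
  for (nm in names(cell$summary))
    expect_equal(back[[nm]]$value, cell$summary[[nm]]$value,
                 tolerance = 1e-12)
  unlink(f)
})

test_that("incomplete datasets are rejected", {
  cell <- fx_cell_noiseless()
  expect_error(assemble_summary(cell$traces[c("Pr2", "Pr3")],
                                cell$protocols, cell$conditions),
               "incomplete")
})
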