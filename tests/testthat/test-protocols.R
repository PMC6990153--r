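test_that("default protocols have the documented sweep counts and durations", {
  prs <- default_protocols()
  expect_equal(vapply(prs[c("Pr2", "Pr3", "Pr4", "Pr5")],
                      function(p) length(p$sweeps), 0L),
               c(Pr2 = 6L, Pr3 = 7L, Pr4 = 16L, Pr5 = 9L))
  expect_equal(sum(vapply(prs[c("Pr2", "Pr3", "Pr4", "Pr5")],
                          protocol_duration, 0)), 228000)
  expect_equal(protocol_duration(prs$Pr7), 8000)
  # Pr7: one sweep, exactly one sinusoid segment with three components
  expect_length(prs$Pr7$sweeps, 1)
  kinds <- vapply(prs$Pr7$sweeps[[1]], function(s) s$kind, "")
  expect_equal(sum(kinds == "sine"), 1)
  sine <- prs$Pr7$sweeps[[1]][[which(kinds == "sine")]]
  expect_length(sine$amplitudes, 3)
})

test_that("voltage_at evaluates each segment kind correctly", {
  pr <- new_protocol("toy", list(list(
    seg_step(100, -80, "hold"),
    seg_sine(100, -30, c(0, 0, 0), c(1, 2, 3), c(0, 0, 0), "sine"),
    seg_sampled(c(0, 10, 20), c(-80, -70, -80), "wave"))), dt = 0.1)
  expect_equal(voltage_at(pr, 1, 50), -80)
  expect_equal(voltage_at(pr, 1, 150), -30)     # zero-amplitude sine
  expect_equal(voltage_at(pr, 1, 205), -75)     # linear interpolation
  expect_error(voltage_at(pr, 1, 1000), "outside")
  # vectorized call agrees with scalar calls
  tt <- c(0, 99.9, 100, 199.9, 200, 219.9)
  expect_equal(voltage_at(pr, 1, tt),
               vapply(tt, function(t) voltage_at(pr, 1, t), 0))
})

test_that("builders honour their configs and reject bad ones", {
  expect_length(build_pr2(list(p1_durations = 500))$sweeps, 1)
  expect_error(build_pr2(list(p1_durations = c(200, 100))), "increasing")
  expect_error(build_pr3(list(p1_voltages = c(0, 0))), "distinct")
  expect_length(build_pr4(list(p3_voltages = -40))$sweeps, 1)
  expect_length(build_pr5(list(p2_voltages = -120))$sweeps, 1)
  # Pr3 P1 voltages strictly increasing in the shipped config
  v3 <- vapply(seq_len(7), function(i)
    ikrfit:::.p_label_value(build_pr3(), i, "P1")$voltage, 0)
  expect_true(all(diff(v3) > 0))
  # zero-amplitude sines make Pr7 piecewise constant
  pr7c <- build_pr7(list(sine_amplitudes = c(0, 0, 0)))
  tt <- seq(2100, 7400, by = 250)
  expect_true(all(voltage_at(pr7c, 1, tt) == -30))
})

test_that("sweeps differ from each other only at the varied element", {
  pr2 <- build_pr2()
  # before P1 starts every sweep commands the same voltage
  tt <- seq(0, 999.9, by = 7)
  for (i in 2:6)
    expect_equal(voltage_at(pr2, i, tt), voltage_at(pr2, 1, tt))
  pr3 <- build_pr3()
  # the tail segment is identical across sweeps
  for (i in seq_len(7)) {
    seg <- ikrfit:::.p_label_value(pr3, i, "tail")
    expect_equal(seg$voltage, -120)
    expect_equal(seg$duration, 500)
  }
  pr4 <- build_pr4()
  for (i in seq_len(16)) {
    expect_equal(ikrfit:::.p_label_value(pr4, i, "P1")$voltage, 40)
    expect_equal(ikrfit:::.p_label_value(pr4, i, "P2")$voltage, -120)
  }
  pr5 <- build_pr5()
  for (i in seq_len(9))
    expect_equal(ikrfit:::.p_label_value(pr5, i, "P1")$duration, 2000)
})

test_that("capacitance mask blanks 5 ms after each discontinuity", {
  pr <- new_protocol("twostep", list(list(
    seg_step(100, -80, "a"), seg_step(100, 40, "b"))), dt = 0.1)
  m <- capacitance_mask(pr)[[1]]
  tt <- (seq_along(m) - 1) * 0.1
  # the window after the step at t = 100 is removed: 50 samples
  expect_equal(sum(!m[tt >= 100 - 1e-9 & tt < 105 - 1e-9]), 50)
  expect_true(all(m[tt >= 105 - 1e-9]))
  # the sweep start is blanked too
  expect_false(m[1])
  # zero window keeps everything
  expect_true(all(capacitance_mask(pr, window = 0)[[1]]))
  # no discontinuity between equal-voltage segments
  pr_eq <- new_protocol("flat", list(list(
    seg_step(50, -80, "a"), seg_step(50, -80, "b"))), dt = 0.1)
  m2 <- capacitance_mask(pr_eq)[[1]]
  expect_true(all(m2[-(1:50)]))
  # sinusoid interior is continuous: only boundaries are blanked
  pr7 <- build_pr7()
  m7 <- capacitance_mask(pr7)[[1]]
  tt7 <- (seq_along(m7) - 1) * pr7$dt
  inside_sine <- tt7 > 2010 & tt7 < 7490
  expect_true(all(m7[inside_sine]))
  # discontinuity-detection oracle: left/right limits at every boundary
  segs <- pr7$sweeps[[1]]
  ends <- cumsum(vapply(segs, function(s) s$duration, 0))
  for (k in 1:(length(segs) - 1)) {
    vl <- ikrfit:::segment_voltage_limits(segs[[k]])[2]
    vr <- ikrfit:::segment_voltage_limits(segs[[k + 1]])[1]
    blanked <- !m7[tt7 >= ends[k] - 1e-9 & tt7 < ends[k] + 5 - 1e-9]
    if (abs(vl - vr) > 1e-9) expect_true(all(blanked))
    else expect_false(any(blanked))
  }
  # idempotent and independent of currents by construction
  expect_identical(capacitance_mask(pr7), capacitance_mask(pr7))
})

test_that("sampled protocols load, round-trip and validate", {
  f <- tempfile(fileext = ".txt")
  writeLines(c("0 -80", "1 0", "2 -80"), f)
  pr <- load_sampled_protocol(f, dt = 0.1)
  expect_equal(protocol_duration(pr), 2)
  expect_equal(voltage_at(pr, 1, 1), 0)
  expect_equal(voltage_at(pr, 1, 0.5), -40)
  # round trip
  f2 <- tempfile(fileext = ".txt")
  write_sampled_protocol(pr, f2)
  pr2 <- load_sampled_protocol(f2, dt = 0.1)
  expect_equal(pr2$sweeps[[1]][[1]]$voltages, pr$sweeps[[1]][[1]]$voltages)
  unlink(c(f, f2))
  # error cases
  f3 <- tempfile(); writeLines(c("0 -80", "2 0", "1 -80"), f3)
  expect_error(load_sampled_protocol(f3), "increasing")
  f4 <- tempfile(); file.create(f4)
  expect_error(load_sampled_protocol(f4))
  unlink(c(f3, f4))
  # the generated AP-like fixture loads without error
  f5 <- tempfile(fileext = ".txt")
  generate_ap_waveform(f5, seed = 1)
  pr6 <- load_sampled_protocol(f5)
  v <- pr6$sweeps[[1]][[1]]$voltages
  expect_true(all(v >= -120 & v <= 60))
  unlink(f5)
})
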