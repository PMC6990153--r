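test_that("transition rates follow the exponential voltage dependence", {
  p <- fx_params()
  # at V = 0 the exponents vanish
  k0 <- transition_rates(p, 0)
  expect_equal(unlist(k0), c(k1 = p[["p1"]], k2 = p[["p3"]],
                             k3 = p[["p5"]], k4 = p[["p7"]]))
  # exponent exactly 1
  p1 <- ikr_params(1, 0.01, 1, 0.01, 1, 0.01, 1, 0.01, 1)
  expect_equal(transition_rates(p1, 100)$k1, exp(1), tolerance = 1e-12)

  # brute-force scalar oracle over a voltage grid and random valid params
  set.seed(1)
  mats <- sample_physiological_params(5, seed = 2)
  for (i in 1:5) {
    pi <- ikr_params(mats[i, ])
    for (V in seq(-120, 60, by = 20)) {
      k <- transition_rates(pi, V)
      expect_equal(k$k1, pi[[1]] * exp(pi[[2]] * V), tolerance = 1e-14)
      expect_equal(k$k2, pi[[3]] * exp(-pi[[4]] * V), tolerance = 1e-14)
      expect_equal(k$k3, pi[[5]] * exp(pi[[6]] * V), tolerance = 1e-14)
      expect_equal(k$k4, pi[[7]] * exp(-pi[[8]] * V), tolerance = 1e-14)
    }
  }
  # overflow guard reports invalid evaluation instead of Inf
  pb <- ikr_params(1, 0.4, 1, 0.4, 1, 0.4, 1, 0.4, 1)
  expect_error(transition_rates(pb, 1e5), "overflow")
})

test_that("gate summary identities and monotonicity hold", {
  p <- fx_params()
  # equal forward/backward rates at V=0 give a_inf = 1/2
  psym <- ikr_params(0.1, 0.02, 0.1, 0.02, 1, 0.01, 1, 0.01, 1)
  expect_equal(gate_summary(psym, 0)$a_inf, 0.5, tolerance = 1e-14)
  # k1 = k2 = 1 gives tau_a = 1/2
  pk <- ikr_params(1, 1e-9, 1, 1e-9, 1, 0.01, 1, 0.01, 1)
  expect_equal(gate_summary(pk, 0)$tau_a, 0.5, tolerance = 1e-9)

  # a_inf strictly increasing, r_inf strictly decreasing (dense grid)
  mats <- sample_physiological_params(5, seed = 3)
  V <- seq(-120, 60, by = 1)
  for (i in 1:5) {
    g <- gate_summary(ikr_params(mats[i, ]), V)
    expect_true(all(diff(g$a_inf) > 0))
    expect_true(all(diff(g$r_inf) < 0))
    # algebraic identities behind the direct summary fit
    k <- transition_rates(ikr_params(mats[i, ]), V)
    expect_equal(g$a_inf / g$tau_a, k$k1, tolerance = 1e-12)
    expect_equal(g$r_inf / g$tau_r, k$k4, tolerance = 1e-12)
  }
})

test_that("Nernst potential matches direct evaluation", {
  expect_equal(nernst(5, 5, 300), 0)
  expect_equal(nernst(130 * exp(1), 130, 300),
               1000 * 8.314462618 * 300 / 96485.33212, tolerance = 1e-12)
  # independent constant-folding oracle
  ek <- nernst(4, 130, 294.65)
  oracle <- 1000 * (8.314462618 * 294.65 / 96485.33212) * log(4 / 130)
  expect_equal(ek, oracle, tolerance = 1e-12)
  expect_true(ek > -89 && ek < -88)
  expect_error(nernst(-1, 130, 300), "positive")
})

test_that("current is conductance * gates * driving force", {
  p <- fx_params()
  expect_equal(ikr_current(p, 0.5, 0.5, -88.4, -88.4), 0)
  expect_equal(ikr_current(p, 0, 1, 0, -88.4), 0)
  expect_equal(ikr_current(ikr_params(c(as.numeric(p)[1:8], 1)),
                           1, 1, -78.4, -88.4), 10)
})

test_that("ODE right-hand side is consistent with the analytic solution", {
  p <- fx_params()
  g <- gate_summary(p, -20)
  # fixed point
  expect_equal(unname(ode_rhs(p, -20, c(g$a_inf, g$r_inf))), c(0, 0),
               tolerance = 1e-14)
  # direct substitution: a = 0, a_inf = 1, tau_a = 2 -> da/dt = 0.5
  # (construct rates giving a_inf ~ 1, tau_a ~ 2 at V = 0)
  pd <- ikr_params(0.5 - 1e-9, 1e-9, 1e-9, 1e-9, 1, 0.01, 1, 0.01, 1)
  expect_equal(unname(ode_rhs(pd, 0, c(0, 0.5))[1]), 0.5, tolerance = 1e-6)

  # central-difference oracle of the analytic solution
  set.seed(4)
  for (rep in 1:5) {
    V <- runif(1, -100, 40)
    s0 <- runif(2)
    h <- 1e-6
    fwd <- analytic_step_solution(p, V, s0, h)
    bwd <- analytic_step_solution(p, V, s0, 0)
    fd <- c((fwd$a - s0[1]) / h, (fwd$r - s0[2]) / h)
    expect_equal(unname(ode_rhs(p, V, s0)), fd, tolerance = 1e-5)
    expect_equal(c(bwd$a, bwd$r), s0, tolerance = 1e-14)
  }
})

test_that("analytic step solution matches an independent RK4 oracle", {
  p <- fx_params()
  rk4 <- function(V, y0, t_end, nstep = 4000) {
    # independent fixed-step integrator written from the rate definitions
    h <- t_end / nstep
    f <- function(y) {
      k1 <- p[[1]] * exp(p[[2]] * V); k2 <- p[[3]] * exp(-p[[4]] * V)
      k3 <- p[[5]] * exp(p[[6]] * V); k4 <- p[[7]] * exp(-p[[8]] * V)
      c(k1 * (1 - y[1]) - k2 * y[1], k4 * (1 - y[2]) - k3 * y[2])
    }
    y <- y0
    for (i in seq_len(nstep)) {
      f1 <- f(y); f2 <- f(y + h / 2 * f1); f3 <- f(y + h / 2 * f2)
      f4 <- f(y + h * f3)
      y <- y + h / 6 * (f1 + 2 * f2 + 2 * f3 + f4)
    }
    y
  }
  set.seed(5)
  for (V in c(-100, -40, 20)) {
    y0 <- runif(2)
    g <- gate_summary(p, V)
    t_end <- 3 * max(g$tau_a, g$tau_r)
    sol <- analytic_step_solution(p, V, y0, t_end)
    expect_equal(c(sol$a, sol$r), rk4(V, y0, t_end), tolerance = 1e-6)
    # long-time limit reaches the steady state
    far <- analytic_step_solution(p, V, y0, 60 * max(g$tau_a, g$tau_r))
    expect_equal(c(far$a, far$r), c(g$a_inf, g$r_inf), tolerance = 1e-14)
  }
})

test_that("semigroup property of the analytic solution", {
  p <- fx_params()
  set.seed(6)
  for (rep in 1:5) {
    V <- runif(1, -110, 50)
    y0 <- runif(2)
    t1 <- runif(1, 1, 500); t2 <- runif(1, 1, 500)
    one <- analytic_step_solution(p, V, y0, t1 + t2)
    mid <- analytic_step_solution(p, V, y0, t1)
    two <- analytic_step_solution(p, V, c(mid$a, mid$r), t2)
    expect_equal(c(one$a, one$r), c(two$a, two$r), tolerance = 1e-12)
  }
})

test_that("parameter validation and serialization round-trip", {
  expect_error(ikr_params(rep(0, 9)), "positive")
  expect_error(ikr_params(c(rep(1, 8), -1)), "positive")
  p <- fx_params()
  f <- tempfile(fileext = ".json")
  write_params(p, f)
  expect_equal(as.numeric(read_params(f)), as.numeric(p), tolerance = 1e-15)
  unlink(f)
})
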