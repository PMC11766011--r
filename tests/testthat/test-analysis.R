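# Analysis chain: sweep features, IV / conductance transform, Boltzmann and
# recovery fits, group statistics.

test_that("sweep features recover analytic peak, time-to-peak and decay50", {
  t <- seq(0, 10, by = 0.05)
  # I(t) = -t * exp(1 - t): peak -1 pA at t = 1 ms
  f <- sweep_features(t, -t * exp(1 - t))
  expect_equal(f$time_to_peak, 1, tolerance = 0.05)
  expect_equal(f$peak, -1, tolerance = 1e-3)

  # instant peak then exponential decay, tau = 2 ms: decay50 = 2 ln 2
  f2 <- sweep_features(t, -exp(-t / 2))
  expect_equal(f2$decay50, 2 * log(2), tolerance = 0.051)

  # monotonically growing magnitude: no 50% decay
  f3 <- sweep_features(t, -t)
  expect_false(f3$decay50_defined)

  f4 <- sweep_features(t, rep(0, length(t)))
  expect_false(f4$defined)
  expect_true(is.na(f4$peak))

  expect_error(sweep_features(t[1:5], rep(1, 5)), ">= 10 samples")
})

test_that("decay50 equals tau*ln(2) over a 10-fold range of time constants", {
  for (tau in c(0.5, 1, 2, 5)) {
    t <- seq(0, 12 * tau, by = 0.05)
    f <- sweep_features(t, -exp(-t / tau))
    expect_equal(f$decay50, tau * log(2), tolerance = 0.06 / (tau * log(2)))
  }
})

test_that("current density is peak over capacitance, linear in both", {
  p <- nav_preset("WT"); p$noise_sd <- 0
  ts <- simulate_protocol(p, protocol_spec("IV"), seed = 1)
  iv10 <- iv_curve(ts, capacitance = 10)
  iv20 <- iv_curve(ts, capacitance = 20)
  expect_equal(iv10$density, iv10$peak / 10)
  expect_equal(iv20$density, iv10$density / 2)
  expect_error(iv_curve(ts, capacitance = -1), "capacitance")

  manual <- data.frame(voltage = -20, peak = -300)
  expect_equal(manual$peak / 10, -30)  # -300 pA at 10 pF -> -30 pA/pF
})

test_that("estimate_vrev interpolates the zero crossing", {
  iv <- data.frame(voltage = c(25, 35, 45), peak = c(-40, -10, 10))
  expect_equal(estimate_vrev(iv), 40)
  iv0 <- data.frame(voltage = c(30, 40, 50), peak = c(-5, 0, 5))
  expect_equal(estimate_vrev(iv0), 40)
  all_in <- data.frame(voltage = c(0, 20, 40), peak = c(-30, -20, -10))
  expect_error(estimate_vrev(all_in), "sign change")
})

test_that("chord conductance: value, exclusion window, degenerate input", {
  iv <- data.frame(voltage = c(-20, 38), peak = c(-300, -1))
  expect_warning(gv <- conductance_curve(iv, v_rev = 40), "dropped")
  expect_equal(nrow(gv), 1)
  expect_equal(gv$g, -300 / (-60))  # 5 nS
  zero <- data.frame(voltage = c(-40, -20, 0), peak = c(0, 0, 0))
  expect_warning(gz <- conductance_curve(zero, v_rev = 40), "normalization")
  expect_true(all(is.na(gz$g_norm)))
})

test_that("fit_boltzmann recovers noiseless parameters exactly", {
  v <- seq(-80, 10, by = 5)
  y <- boltzmann(v, -38.4, 5.4, "activation")
  fit <- fit_boltzmann(v, y, "activation")
  expect_equal(fit$v_half, -38.4, tolerance = 1e-6)
  expect_equal(fit$k, 5.4, tolerance = 1e-6)
  expect_false(fit$low_confidence)

  # availability form
  va <- seq(-120, 10, by = 5)
  ya <- boltzmann(va, -86.6, 5.6, "availability")
  fa <- fit_boltzmann(va, ya, "availability")
  expect_equal(fa$v_half, -86.6, tolerance = 1e-6)
  expect_equal(fa$k, 5.6, tolerance = 1e-6)

  # hand values: y(v_half + k ln 9) = 0.9; y(v_half) = 0.5
  expect_equal(boltzmann(-38.4 + 5.4 * log(9), -38.4, 5.4, "activation"),
               0.9, tolerance = 1e-9)
  expect_equal(boltzmann(-38.4, -38.4, 5.4, "activation"), 0.5)
})

test_that("Boltzmann fits are equivariant under shifts and y-scaling", {
  set.seed(3)
  v <- seq(-80, 10, by = 5)
  y <- boltzmann(v, -41, 6.2, "activation") + stats::rnorm(length(v), 0, 0.01)
  f0 <- fit_boltzmann(v, y, "activation")
  fshift <- fit_boltzmann(v + 13, y, "activation")
  expect_equal(fshift$v_half, f0$v_half + 13, tolerance = 1e-6)
  expect_equal(fshift$k, f0$k, tolerance = 1e-6)
  fscale <- fit_boltzmann(v, 3.7 * y, "activation")
  expect_equal(fscale$v_half, f0$v_half, tolerance = 1e-4)
  expect_equal(fscale$k, f0$k, tolerance = 1e-4)

  expect_error(fit_boltzmann(v[1:3], y[1:3]), ">= 5")
})

test_that("fit_recovery recovers noiseless parameters and model limits", {
  dt <- exp(seq(log(1), log(3000), length.out = 12))
  r <- 1 - 0.6 * exp(-dt / 24.51) - 0.4 * exp(-dt / 241.1)
  fit <- fit_recovery(dt, r)
  expect_equal(fit$a_fast, 0.6, tolerance = 1e-4)
  expect_equal(fit$tau_fast, 24.51, tolerance = 1e-4)
  expect_equal(fit$tau_slow, 241.1, tolerance = 1e-4)
  model <- function(t) {
    fit$plateau * (1 - fit$a_fast * exp(-t / fit$tau_fast) -
                     (1 - fit$a_fast) * exp(-t / fit$tau_slow))
  }
  expect_equal(model(0), 0, tolerance = 1e-6)
  expect_equal(model(1e6), 1, tolerance = 1e-6)

  w <- capture_warnings(fit_recovery(dt, rep(1, 12)))
  expect_true(any(grepl("degenerate", w)))
  expect_error(fit_recovery(dt[1:4], r[1:4]), ">= 6")
  expect_error(fit_recovery(seq(10, 20, length.out = 8), r[1:8]), "decade")
})

test_that("compare_groups matches hand-derived statistics", {
  same <- compare_groups(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)

  # capacitance summaries: |t| = 0.6 / sqrt(0.5^2 + 0.8^2) = 0.64
  g <- compare_groups(list(mean = 8.6, sem = 0.5, n = 32),
                      list(mean = 9.2, sem = 0.8, n = 21))
  expect_equal(abs(g$t), 0.636, tolerance = 0.01)
  expect_gt(g$p, 0.05)

  a <- c(1.2, 3.1, 2.2, 4.5); b <- c(2.0, 2.8, 3.6)
  ab <- compare_groups(a, b); ba <- compare_groups(b, a)
  expect_equal(ab$t, -ba$t)
  expect_equal(ab$p, ba$p)
  # pooled-variance contract: agrees with the classical two-sample t
  ref <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(ab$t, unname(ref$statistic))
  expect_equal(ab$p, ref$p.value)
})

test_that("robust_peak is calibrated on signal-free and signal sweeps", {
  set.seed(42)
  # pure noise: extremum is badly biased, split estimator is centred near 0
  raw <- replicate(400, {
    y <- stats::rnorm(800, 0, 50)
    c(naive = y[which.max(abs(y))], split = robust_peak(y))
  })
  expect_gt(mean(abs(raw["naive", ])), 120)
  expect_lt(abs(mean(raw["split", ])), 12)

  # sharp noisy peak: estimator stays within a few percent of truth
  t <- seq(0, 20, by = 0.05)
  shape <- -(1 - exp(-t / 0.2)) * exp(-t / 2) * 1000
  est <- replicate(200, robust_peak(shape + stats::rnorm(length(t), 0, 40)))
  expect_lt(abs(mean(est) - min(shape)) / abs(min(shape)), 0.03)
})
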