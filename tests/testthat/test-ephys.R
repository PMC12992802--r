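test_that("drug_shift recovers exact steps on noise-free staircases", {
  g <- make_staircase(s1 = 5, s2 = 5)
  expect_equal(drug_shift(g$trace, c("base", "TTX")), 5, tolerance = 1e-3)
  expect_equal(drug_shift(g$trace, "TTX->GBZ"), 5, tolerance = 1e-3)
  g0 <- make_staircase(s1 = 0, s2 = 0)
  expect_equal(drug_shift(g0$trace, c("base", "TTX")), 0,
               tolerance = 1e-6)
  # windowing errors
  expect_error(drug_shift(g$trace, c("base", "TTX"), pre_window = 200),
               "window")
  expect_error(drug_shift(g$trace, c("base", "GBZ")), "precede")
})

test_that("drug_shift matches a ground-truth-masked mean oracle under
          IPSCs and noise", {
  set.seed(41)
  ipsc <- sort(stats::runif(450, 1, 148))
  tr <- trace_ground_truth(-200, c("base->TTX" = 8, "TTX->GBZ" = 5),
                           ipsc_times = ipsc, ipsc_amplitudes = 30,
                           noise_sd = 2)
  g <- gen_tonic_trace(c("TTX", "GBZ"), tr, 450, rate = 200, seed = 42)
  est <- drug_shift(g$trace, c("base", "TTX"))
  # oracle: average only samples at least 60 ms after any true IPSC
  clean <- function(t0, t1) {
    tt <- g$trace$t
    idx <- which(tt >= t0 & tt <= t1)
    ok <- vapply(tt[idx], function(x) {
      prev <- ipsc[ipsc <= x]
      length(prev) == 0 || x - max(prev) > 0.06
    }, logical(1))
    mean(g$trace$I[idx[ok]])
  }
  oracle <- clean(210, 240) - clean(120, 150)
  expect_lt(abs(est - 8), 0.5)
  expect_lt(abs(est - oracle), 0.5)
})

test_that("decompose_tonic recovers randomized shifts and the
          TTX-sensitive fraction", {
  err <- c(); ferr <- c()
  for (s in 1:20) {
    tr <- random_trace_truth(c("TTX", "GBZ"), 450, seed = s,
                             noise_sd = 2)
    g <- gen_tonic_trace(c("TTX", "GBZ"), tr, 450, rate = 200,
                         seed = s + 500)
    d <- decompose_tonic(g$trace, "ttx-gbz")
    truth <- tr$component_shifts[names(d$shifts)]
    err <- c(err, d$shifts - truth)
    ferr <- c(ferr, d$ttx_sensitive_fraction - truth[1] / sum(truth))
    # additivity is exact by construction
    expect_equal(d$ttx_sensitive_pA + d$ttx_insensitive_pA,
                 d$total_tonic_pA)
  }
  expect_lt(max(abs(err)), 0.5)
  expect_lt(max(abs(ferr)), 0.03)
})

test_that("decomposition books the printed young fraction from its shifts", {
  g <- make_staircase(s1 = 6.35, s2 = 3.65)
  d <- decompose_tonic(g$trace, "ttx-gbz")
  expect_equal(d$ttx_sensitive_fraction, 0.635, tolerance = 1e-3)
  # zero TTX component gives fraction 0; negative components are
  # reported as-is and flagged
  gz <- make_staircase(s1 = 0, s2 = 10)
  expect_equal(decompose_tonic(gz$trace)$ttx_sensitive_fraction, 0,
               tolerance = 1e-3)
  gn <- make_staircase(s1 = -2, s2 = 10)
  dn <- decompose_tonic(gn$trace)
  expect_equal(dn$ttx_sensitive_pA, -2, tolerance = 0.05)
  expect_identical(dn$negative_components, "base->TTX")
})

test_that("IPSC detector finds injected events and rejects flat traces", {
  g0 <- make_staircase(s1 = 0, s2 = 10, rate = 500, duration = 150)
  expect_length(detect_ipscs(g0$trace, c(0, 50))$times, 0)

  set.seed(43)
  times <- sort(stats::runif(50, 1, 49))
  times <- times[c(TRUE, diff(times) > 0.02)]
  g <- make_staircase(s1 = 0, s2 = 10, noise = 2, rate = 500,
                      duration = 150, ipsc_times = times, seed = 44)
  ev <- detect_ipscs(g$trace, c(0, 50))
  hits <- vapply(times, function(tt) any(abs(ev$times - tt) <= 0.005),
                 logical(1))
  fp <- sum(vapply(ev$times, function(tt) all(abs(times - tt) > 0.005),
                   logical(1)))
  expect_gte(sum(hits), length(times) - 2)
  expect_lte(fp, 1)
  expect_equal(ev$mean_amplitude_pA, 30, tolerance = 0.15)
  # window after GABA-A blockade is a protocol error
  expect_error(detect_ipscs(g$trace, c(0, 120)), "blockade")
})

test_that("detected IPSC frequency matches the injected rate", {
  set.seed(45)
  n <- stats::rpois(1, 2 * 120)
  times <- sort(stats::runif(n, 0.5, 119.5))
  times <- times[c(TRUE, diff(times) > 0.02)]
  g <- gen_tonic_trace(
    c("GBZ"), trace_ground_truth(-200, c("base->GBZ" = 10),
                                 ipsc_times = times,
                                 ipsc_amplitudes = 30, noise_sd = 2),
    duration = 360, rate = 500, seed = 46, event_times = 240)
  ev <- detect_ipscs(g$trace, c(0, 120))
  expect_equal(ev$frequency_Hz, length(times) / 120, tolerance = 0.05)
})

test_that("frequency-current regression equals the closed-form normal
          equations", {
  # trivial cases
  fit <- fit_freq_current_regression(1:3, c(2, 4, 6))
  expect_equal(fit$slope, 2)
  expect_equal(fit$r_squared, 1)
  expect_equal(fit_freq_current_regression(1:5, rep(3, 5))$r_squared, 0)
  expect_error(fit_freq_current_regression(rep(1, 4), 1:4), "degenerate")
  # oracle equivalence on random inputs
  set.seed(47)
  for (i in 1:5) {
    x <- stats::rnorm(30); y <- 2 + 0.5 * x + stats::rnorm(30)
    fit <- fit_freq_current_regression(x, y)
    X <- cbind(1, x)
    beta <- solve(t(X) %*% X, t(X) %*% y)
    res <- y - X %*% beta
    r2 <- 1 - sum(res^2) / sum((y - mean(y))^2)
    tstat <- beta[2] / sqrt(sum(res^2) / 28 / sum((x - mean(x))^2))
    expect_equal(fit$intercept, beta[1], tolerance = 1e-10)
    expect_equal(fit$slope, beta[2], tolerance = 1e-10)
    expect_equal(fit$r_squared, r2, tolerance = 1e-10)
    expect_equal(fit$p_value, 2 * stats::pt(-abs(tstat), 28),
                 tolerance = 1e-10)
  }
})

test_that("reversal potential interpolation finds the zero crossing", {
  V <- seq(-80, -50, by = 5)
  expect_equal(reversal_from_iv(V, V + 65), -65)
  expect_equal(reversal_from_iv(V, 2 * (V + 80)), -80)
  expect_error(reversal_from_iv(V, V + 200), "sign")
  # Monte-Carlo: noisy line crossings centre on the analytic crossing
  set.seed(48)
  vr <- replicate(20, reversal_from_iv(V, (V + 65) + stats::rnorm(7, 0, 1)))
  expect_lt(abs(mean(vr) - (-65)), 1)
  expect_lt(max(abs(vr - (-65))), 3)
})

test_that("E_xGABA combination follows the stated driving-force convention", {
  expect_equal(estimate_exgaba(-80, 15)$E_xGABA_mV, -95)
  expect_equal(estimate_exgaba(-80, 0)$E_xGABA_mV, -80)
  # the printed young value arises from Vm -80 with a -15 mV DF
  expect_equal(estimate_exgaba(-80, -15)$E_xGABA_mV, -65)
  expect_equal(estimate_exgaba(-80, 15, "e-minus-vm")$E_xGABA_mV, -65)
})

test_that("shift estimator is unbiased over many seeds", {
  errs <- vapply(1:60, function(s) {
    tr <- trace_ground_truth(-200, c("base->TTX" = 6, "TTX->GBZ" = 4),
                             noise_sd = 2)
    g <- gen_tonic_trace(c("TTX", "GBZ"), tr, 450, rate = 100, seed = s)
    drug_shift(g$trace, c("base", "TTX")) - 6
  }, numeric(1))
  expect_lt(abs(mean(errs)), 0.1)
})
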