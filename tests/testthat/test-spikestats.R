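test_that("rate kernel is unit-area and conserves the spike count", {
  # single spike integrates to one spike per cell
  r <- estimate_rate(0.5, sigma_ms = 20, n_cells = 1, duration = 1)
  expect_equal(sum(r$rate) * 0.001, 1, tolerance = 0.01)
  # count conservation under edge renormalization, spikes near edges
  set.seed(1)
  sp <- spike_data(sample(1:50, 400, TRUE), stats::runif(400, 0, 2),
                   50, 2, "GC")
  r2 <- estimate_rate(sp)
  expect_equal(sum(r2$rate) * 0.001 * 50, 400, tolerance = 0.01)
  # sigma -> 0 equals the raw histogram
  r0 <- estimate_rate(sp, sigma_ms = 0)
  counts <- tabulate(pmin(2000, floor(sp$time / 0.001) + 1), 2000)
  expect_equal(r0$rate, counts / (50 * 0.001))
})

test_that("homogeneous Poisson rate is estimated without bias", {
  set.seed(2)
  n_cells <- 100; dur <- 10; lam <- 20
  n <- stats::rpois(1, n_cells * dur * lam)
  sp <- spike_data(sample(1:n_cells, n, TRUE), stats::runif(n, 0, dur),
                   n_cells, dur, "MF")
  r <- estimate_rate(sp)
  expect_lt(abs(mean(r$rate) - lam), 1)
})

test_that("ON/OFF classification equals a brute-force edge scan", {
  geom <- build_geometry(0.05, seed = 3)
  cfg <- condition_config("adult-wt")
  conn <- build_connectivity(geom, cfg, seed = 4)
  # whole sheet ON, empty-ish corner OFF
  all_on <- classify_on_off(conn, input_protocol(
    c(0, geom$dims_mm[1], 0, geom$dims_mm[2])))
  expect_true(all(all_on == "ON"))
  zone <- c(0, 0.3, 0, 0.4) * geom$dims_mm[c(1, 1, 2, 2)]
  lab <- classify_on_off(conn, input_protocol(zone))
  in_zone <- geom$mf_pos[, 1] >= zone[1] & geom$mf_pos[, 1] <= zone[2] &
    geom$mf_pos[, 2] >= zone[3] & geom$mf_pos[, 2] <= zone[4]
  brute <- vapply(seq_len(geom$counts[["GC"]]), function(i) {
    pres <- conn$mf_to_gc$pre[conn$mf_to_gc$post == i]
    if (any(in_zone[pres])) "ON" else "OFF"
  }, "")
  expect_identical(lab, brute)
})

test_that("input-output correlation behaves on constructed series", {
  t <- seq(0.0005, 10, by = 0.001)
  a <- list(t = t, rate = 5 + sin(t), sigma_ms = 20, bin_ms = 1,
            n_cells = 1, population = "")
  class(a) <- "rate_estimate"
  b <- a; b$rate <- 3 - 2 * sin(t)
  expect_equal(input_output_correlation(a, a), 1)
  expect_equal(input_output_correlation(a, b), -1)
  set.seed(5)
  w1 <- a; w1$rate <- stats::rnorm(length(t))
  w2 <- a; w2$rate <- stats::rnorm(length(t))
  expect_lt(abs(input_output_correlation(w1, w2)), 0.1)
  cz <- a; cz$rate <- rep(1, length(t))
  expect_warning(rz <- input_output_correlation(a, cz), "zero-variance")
  expect_true(is.na(rz))
})

test_that("power split separates input-driven from oscillation bands", {
  t <- seq(0.0005, 20, by = 0.001)
  mk <- function(x) structure(list(t = t, rate = x, sigma_ms = 0,
                                   bin_ms = 1, n_cells = 1,
                                   population = ""),
                              class = "rate_estimate")
  # pure input-frequency sinusoid: negligible oscillation power
  ps1 <- power_split(mk(10 + 3 * sin(2 * pi * 2 * t)), 2,
                     remove_locked = FALSE, floor_band = NULL)
  expect_lt(ps1$P_osc / ps1$P_input, 0.01)
  # pure 30-Hz sinusoid: negligible input power
  ps2 <- power_split(mk(10 + 3 * sin(2 * pi * 30 * t)), 2,
                     remove_locked = FALSE, floor_band = NULL)
  expect_lt(ps2$P_input / ps2$P_osc, 0.01)
  # 2:1 amplitude mixture gives 4:1 power (Parseval)
  ps3 <- power_split(mk(10 + 4 * sin(2 * pi * 2 * t) +
                          2 * sin(2 * pi * 30 * t)), 2,
                     remove_locked = FALSE, floor_band = NULL)
  expect_equal(ps3$P_input / ps3$P_osc, 4, tolerance = 0.1)
  # the locked-component removal keeps rhythms that are not phase-locked
  # to the stimulus (incommensurate frequency)
  x4 <- 10 + 4 * sin(2 * pi * 2 * t) + 2 * sin(2 * pi * 31.3 * t + 1)
  ps4a <- power_split(mk(x4), 2, floor_band = NULL)
  ps4b <- power_split(mk(x4), 2, floor_band = NULL,
                      remove_locked = FALSE)
  expect_equal(ps4a$P_osc, ps4b$P_osc, tolerance = 0.15)
  # a peak outside the default band widens it (and is recorded)
  ps5 <- power_split(mk(10 + 3 * sin(2 * pi * 60 * t)), 2,
                     remove_locked = FALSE, floor_band = NULL)
  expect_true(ps5$band_widened)
  expect_gte(ps5$osc_band[2], 60)
  expect_error(power_split(mk(t), 2, osc_band = c(2, 50)), "overlap")
})

test_that("bootstrap sem matches the CLT and is reproducible", {
  expect_equal(bootstrap_sem(rep(3, 10), seed = 1)$sem, 0)
  set.seed(6)
  x <- stats::rnorm(100)
  b <- bootstrap_sem(x, mean, n_iter = 1000, seed = 2)
  expect_lt(abs(b$sem - stats::sd(x) / 10), 0.2 * stats::sd(x) / 10)
  expect_identical(b, bootstrap_sem(x, mean, n_iter = 1000, seed = 2))
  expect_lt(b$ci95[1], b$ci95[2])
})
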