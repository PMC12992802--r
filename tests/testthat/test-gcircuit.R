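conds <- lapply(c("young-wt", "young-ko", "adult-wt", "adult-ko"),
                condition_config)
names(conds) <- vapply(conds, `[[`, "", "name")

test_that("canonical configs reproduce the measured structure", {
  expect_equal(conds[["adult-wt"]]$goc_convergence_mean, 8)
  expect_equal(conds[["adult-ko"]]$goc_convergence_mean, 8)
  expect_equal(conds[["young-wt"]]$goc_convergence_mean, 32)   # 4 x 8
  expect_equal(conds[["young-ko"]]$goc_convergence_mean, 24)   # 3 x 8
  # miniature rate ratios: adult/young = 1/3 (WT), 1/2 (KO)
  expect_equal(conds[["adult-wt"]]$spont_release_rate_Hz /
                 conds[["young-wt"]]$spont_release_rate_Hz, 1 / 3)
  expect_equal(conds[["adult-ko"]]$spont_release_rate_Hz /
                 conds[["young-ko"]]$spont_release_rate_Hz, 1 / 2)
  # reversal shift with age
  expect_equal(conds[["young-wt"]]$E_xGABA_mV, -65)
  expect_equal(conds[["adult-wt"]]$E_xGABA_mV, -80)
  expect_lt(conds[["adult-wt"]]$E_xGABA_mV,
            conds[["young-wt"]]$E_xGABA_mV)
  # KO reduces the activity-independent conductance; K+ gain >= 1
  for (age in c("young", "adult")) {
    expect_lt(conds[[paste0(age, "-ko")]]$g_tonic_const_nS,
              conds[[paste0(age, "-wt")]]$g_tonic_const_nS)
    expect_gte(conds[[paste0(age, "-ko")]]$k_current_gain, 1)
  }
  expect_error(condition_config("embryonic", "WT"))
})

test_that("homeostatic K+ gain restores the wild-type rheobase", {
  for (age in c("young", "adult")) {
    r_wt <- rheobase_gc(conds[[paste0(age, "-wt")]])
    r_ko <- rheobase_gc(conds[[paste0(age, "-ko")]])
    expect_equal(r_ko, r_wt, tolerance = 0.02)
  }
  # without compensation the KO would be more excitable
  ko_uncomp <- conds[["adult-ko"]]
  ko_uncomp$k_current_gain <- 1
  expect_lt(rheobase_gc(ko_uncomp), rheobase_gc(conds[["adult-wt"]]))
})

test_that("stochastic release obeys its probability and Poisson minis", {
  cfg <- conds[["adult-wt"]]
  cfg1 <- cfg; cfg1$evoked_release_prob <- 1
  cfg1$spont_release_rate_Hz <- 0
  sp <- list(c(0.1, 0.5, 0.9), c(0.2, 0.7))
  rel <- sample_goc_gc_release(sp, cfg1, 1, seed = 1)
  expect_equal(rel$times, sort(unlist(sp)))
  cfg0 <- cfg1; cfg0$evoked_release_prob <- 0
  expect_length(sample_goc_gc_release(sp, cfg0, 1, seed = 1)$times, 0)
  # Poisson count oracle: 8 synapses at 2 Hz for 100 s
  cfgp <- cfg; cfgp$evoked_release_prob <- 0
  cfgp$spont_release_rate_Hz <- 2
  n <- length(sample_goc_gc_release(rep(list(numeric(0)), 8), cfgp, 100,
                                    seed = 2)$times)
  expect_lt(abs(n - 1600), 3 * sqrt(1600))
  # determinism
  r1 <- sample_goc_gc_release(sp, cfg, 1, seed = 5)
  r2 <- sample_goc_gc_release(sp, cfg, 1, seed = 5)
  expect_identical(r1, r2)
})

test_that("tonic conductance follows the two-source model", {
  cfg <- conds[["young-wt"]]
  # no releases: constant at the activity-independent level
  g0 <- tonic_conductance_trace(numeric(0), cfg, dt_ms = 1, duration = 1)
  expect_true(all(g0$g == cfg$g_tonic_const_nS))
  # single release decays by 1/e after one time constant
  g1 <- tonic_conductance_trace(0.05, cfg, dt_ms = 1, duration = 1)
  at <- function(t) g1$g[which.min(abs(g1$t - t))]
  expect_equal(at(0.05 + cfg$spill_tau_ms / 1000) - cfg$g_tonic_const_nS,
               cfg$spill_gain_nS_per_event / exp(1),
               tolerance = 0.01 * cfg$spill_gain_nS_per_event)
  expect_error(tonic_conductance_trace(0.05, cfg, dt_ms = 50,
                                       duration = 1), "dt_ms")
})

test_that("mean spillover matches Campbell's theorem for Poisson input", {
  cfg <- conds[["young-wt"]]
  lambda <- 50
  set.seed(6)
  rel <- sort(stats::runif(stats::rpois(1, lambda * 200), 0, 200))
  g <- tonic_conductance_trace(rel, cfg, dt_ms = 5, duration = 200)
  expected <- lambda * cfg$spill_gain_nS_per_event *
    cfg$spill_tau_ms / 1000
  measured <- mean(g$g[g$t > 1]) - cfg$g_tonic_const_nS
  expect_lt(abs(measured - expected) / expected, 0.05)
})

test_that("convergence estimation inverts the analytic mean current", {
  cfg <- conds[["adult-wt"]]
  # analytic mean current at N = 8 from Campbell's theorem
  lam1 <- cfg$background_goc_rate_Hz * cfg$evoked_release_prob +
    cfg$spont_release_rate_Hz
  DF <- -60 - cfg$E_xGABA_mV
  target8 <- (cfg$g_tonic_const_nS +
                8 * lam1 * cfg$spill_gain_nS_per_event *
                cfg$spill_tau_ms / 1000) * DF
  N <- estimate_required_convergence(cfg, target8, holding_mV = -60,
                                     seed = 3)
  expect_lte(abs(N - 8), 1)
  # a tiny target with no constant conductance needs a single synapse
  cfg0 <- cfg; cfg0$g_tonic_const_nS <- 0
  expect_equal(estimate_required_convergence(cfg0, 1e-6, seed = 3), 1L)
  expect_error(estimate_required_convergence(cfg, -1), "> 0")
  expect_error(estimate_required_convergence(cfg, 1e9, N_max = 64),
               "unreachable")
})

test_that("required convergence is monotone in the target current", {
  cfg <- conds[["adult-wt"]]
  set.seed(9)
  targets <- sort(stats::runif(25, 5, 80))
  Ns <- vapply(targets, function(tg)
    estimate_required_convergence(cfg, tg, seed = 11, sim_duration = 20),
    integer(1))
  expect_true(all(diff(Ns) >= 0))
})
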