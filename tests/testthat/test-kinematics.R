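# small synthetic skeleton with exact geometry for angle checks
make_pose <- function(fore_l = c(0, 3, 0)) {
  n <- 4
  pos <- array(0, c(n, 9, 3))
  # body axis along +x at height 2: anus (0,0,2) -> neck (4.5,0,2)
  pos[, 4, ] <- matrix(c(5, 5, 2), n, 3, byrow = TRUE)
  pos[, 2, ] <- matrix(c(9.5, 5, 2), n, 3, byrow = TRUE)
  pos[, 3, ] <- matrix(c(7.8, 5, 2), n, 3, byrow = TRUE)
  pos[, 1, ] <- matrix(c(11.2, 5, 2.5), n, 3, byrow = TRUE)
  pos[, 5, ] <- matrix(c(2, 5, 1), n, 3, byrow = TRUE)
  for (m in 6:9) pos[, m, ] <- matrix(c(7, 5, 1), n, 3, byrow = TRUE)
  # left forepaw placed relative to the chest by the requested offset
  pos[, 6, ] <- matrix(c(7.8, 5, 2) + fore_l, n, 3, byrow = TRUE)
  skeleton_3d((0:(n - 1)) / 20, pos)
}

test_that("limb angles follow the vector geometry", {
  # limb vector parallel to the body axis: 0 degrees
  a_par <- limb_angle_series(make_pose(c(3, 0, 0)))
  expect_equal(unname(a_par$angle_deg[1, "LF"]), 0, tolerance = 1e-6)
  # orthogonal: 90 degrees
  a_orth <- limb_angle_series(make_pose(c(0, 3, 0)))
  expect_equal(unname(a_orth$angle_deg[1, "LF"]), 90, tolerance = 1e-6)
  # static pose: zero angular speed
  expect_equal(max(a_orth$speed_deg_s), 0)
})

test_that("angular speed recovers a known sinusoid within the
          central-difference attenuation", {
  f <- 1; A <- 20
  n <- 400
  t <- (0:(n - 1)) / 20
  base <- make_pose()
  pos <- base$pos[rep(1, n), , ]
  ang <- (45 + A * sin(2 * pi * f * t)) * pi / 180
  pos[, 6, 1] <- pos[, 3, 1] + 3 * cos(ang)
  pos[, 6, 2] <- pos[, 3, 2] + 3 * sin(ang)
  pos[, 6, 3] <- pos[, 3, 3]
  sk <- skeleton_3d(t, pos)
  sp <- limb_angle_series(sk)$speed_deg_s[, "LF"]
  # analytic peak speed 2 pi f A, attenuated by sinc(2 pi f dt)
  atten <- sin(2 * pi * f / 20) / (2 * pi * f / 20)
  expect_equal(max(sp[10:(n - 10)]), 2 * pi * f * A * atten,
               tolerance = 0.05 * 2 * pi * f * A)
})

test_that("rapid-motion mask equals the brute-force per-frame rule", {
  g <- gen_skeleton(gait_ground_truth(rear_episodes = list(c(20, 25))),
                    60, seed = 3)
  sk <- g$skeleton
  m <- rapid_motion_mask(sk)
  # brute force re-implementation, frame by frame
  P <- sk$pos
  n <- dim(P)[1]
  anus <- P[, "anus", ]
  v <- rbind(anus[2, ] - anus[1, ],
             (anus[-(1:2), ] - anus[seq_len(n - 2), ]) / 2,
             anus[n, ] - anus[n - 1, ]) * 20
  spd <- sqrt(rowSums(v^2))
  lim <- 2.576 * stats::sd(P[, "l_hindpaw", "z"] - P[, "r_hindpaw", "z"])
  brute <- logical(n)
  for (i in seq_len(n)) {
    ref <- max(P[i, "l_hindpaw", "z"], P[i, "r_hindpaw", "z"])
    brute[i] <- spd[i] > 2 &&
      P[i, "l_forepaw", "z"] <= ref + lim &&
      P[i, "r_forepaw", "z"] <= ref + lim
  }
  expect_identical(m$mask, brute)
  # rearing frames are excluded, sustained walking retained
  rear <- sk$t > 20.5 & sk$t < 24.5
  expect_true(!any(m$mask[rear]))
  expect_gt(mean(m$mask[!rear]), 0.8)
  # a stationary skeleton yields an empty mask
  frozen <- sk
  frozen$pos <- sk$pos[rep(1, n), , ]
  expect_true(!any(rapid_motion_mask(frozen)$mask))
})

test_that("left-right speed correlation tracks the phase mix", {
  corr_at <- function(mix, seed = 1) {
    g <- gen_skeleton(gait_ground_truth(lr_phase_mix = mix), 60,
                      seed = seed)
    a <- limb_angle_series(g$skeleton)
    m <- rapid_motion_mask(g$skeleton)
    limb_speed_correlations(a, m)$r["LF", "RF"]
  }
  cc <- vapply(c(0, 0.25, 0.5, 0.75, 1), corr_at, numeric(1))
  expect_lt(cc[1], 0)          # pure antiphase
  expect_gt(cc[5], 0.9)        # pure in-phase
  expect_true(all(diff(cc) > 0))  # strictly increasing in the mix
  # matrix structure
  g <- gen_skeleton(gait_ground_truth(), 60, seed = 2)
  cm <- limb_speed_correlations(limb_angle_series(g$skeleton),
                                rapid_motion_mask(g$skeleton))
  expect_equal(cm$r, t(cm$r))
  expect_equal(unname(diag(cm$r)), rep(1, 4))
  expect_error(limb_speed_correlations(limb_angle_series(g$skeleton),
                                       rep(FALSE, 1200)),
               "insufficient")
})

test_that("phase mix recovery rank-correlates across recordings", {
  set.seed(9)
  mixes <- stats::runif(20)
  cc <- vapply(seq_along(mixes), function(i) {
    g <- gen_skeleton(gait_ground_truth(lr_phase_mix = mixes[i]), 60,
                      seed = i)
    a <- limb_angle_series(g$skeleton)
    m <- rapid_motion_mask(g$skeleton)
    limb_speed_correlations(a, m)$r["LF", "RF"]
  }, numeric(1))
  expect_gt(stats::cor(mixes, cc, method = "spearman"), 0.9)
})

test_that("segmentation finds the walk-to-stillness transition", {
  g <- gen_skeleton(gait_ground_truth(), 60, seed = 1)
  P <- g$skeleton$pos
  n <- dim(P)[1]
  PP <- array(NA_real_, c(2 * n, 9, 3))
  PP[1:n, , ] <- P
  set.seed(2)
  PP[(n + 1):(2 * n), , ] <- P[rep(n, n), , ] +
    array(stats::rnorm(n * 27, 0, 0.03), c(n, 9, 3))
  skel <- skeleton_3d(seq(0, by = 1 / 20, length.out = 2 * n), PP)
  seg <- segment_movements(skel)
  expect_length(seg$changepoints_s, 1)
  expect_lt(abs(seg$changepoints_s - 60), 1)
  # constant behavior: a single segment
  expect_equal(nrow(segment_movements(g$skeleton)$segments), 1)
  # determinism
  expect_identical(segment_movements(skel, seed = 5)$segments,
                   segment_movements(skel, seed = 5)$segments)
  expect_error(segment_movements(gen_skeleton(gait_ground_truth(), 20,
                                              seed = 1)$skeleton),
               "30 s")
})

test_that("positive-correlation probability rises with turning speed
          when the generator couples them", {
  tp <- rep(c(0, 40, 80, 120, 160, 200), 4)
  g <- gen_skeleton(gait_ground_truth(turning_profile = tp,
                                      lr_phase_mix = tp / 200),
                    240, seed = 7)
  pc <- positive_corr_vs_turning(g$skeleton,
                                 segment_movements(g$skeleton))
  p <- pc$curve$p_positive[pc$curve$n_segments > 0]
  expect_true(all(diff(p) >= 0))
  expect_gt(p[length(p)], p[1])
})

test_that("turning-independent and antiphase constructions give flat
          and zero curves", {
  tp <- rep(c(0, 40, 80, 120, 160, 200), 4)
  set.seed(11)
  g_null <- gen_skeleton(gait_ground_truth(turning_profile = tp,
                                           lr_phase_mix = sample(tp / 200)),
                         240, seed = 8)
  pc_null <- positive_corr_vs_turning(g_null$skeleton,
                                      segment_movements(g_null$skeleton))
  cn <- pc_null$curve[pc_null$curve$n_segments > 0, ]
  # flat within the bootstrap CI: spread does not exceed combined sems
  expect_lt(max(cn$p_positive) - min(cn$p_positive),
            2 * 1.96 * max(cn$sem) + 1e-9)
  # all-antiphase: zero probability in every bin
  g0 <- gen_skeleton(gait_ground_truth(turning_profile = tp,
                                       lr_phase_mix = 0), 240, seed = 9)
  pc0 <- positive_corr_vs_turning(
    g0$skeleton, segment_movements(g0$skeleton, penalty_mult = 1))
  expect_true(all(pc0$curve$p_positive[pc0$curve$n_segments > 0] == 0))
})

test_that("gait metrics behave on constructed gaits", {
  # perfectly periodic: zero stride-time CV and phase variance
  g <- gen_skeleton(gait_ground_truth(marker_noise_sd = 0), 120,
                    seed = 4)
  gm <- gait_metrics(g$skeleton)
  expect_equal(gm$stride_time_cv, 0, tolerance = 1e-8)
  # phase lags are quantized at the 20-Hz frame grid; occasional
  # one-frame peak shifts near walls bound the residual variance
  expect_lt(gm$interlimb_phase_variance, 0.05)
  expect_gte(gm$n_strides, 20)
  # 10% stride-interval jitter appears as the stride-time CV
  gj <- gen_skeleton(gait_ground_truth(stride_jitter = 0.10,
                                       marker_noise_sd = 0.02), 120,
                     seed = 5)
  expect_lt(abs(gait_metrics(gj$skeleton)$stride_time_cv - 0.10), 0.02)
  # doubling placement noise strictly increases the ataxia index
  ai <- vapply(c(0.1, 0.2, 0.4), function(pn) {
    gp <- gen_skeleton(gait_ground_truth(placement_noise_sd = pn,
                                         marker_noise_sd = 0.02), 120,
                       seed = 6)
    gait_metrics(gp$skeleton)$ataxia_index
  }, numeric(1))
  expect_true(all(diff(ai) > 0))
  # too short a recording: insufficient strides
  expect_error(gait_metrics(gen_skeleton(gait_ground_truth(), 5,
                                         seed = 1)$skeleton),
               "insufficient")
})
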