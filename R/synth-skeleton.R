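#' Marker names of the 9-point skeleton
#'
#' Fixed marker order used by all skeleton containers and files: nose,
#' neck, chest, anus, tail tip, left/right forepaw, left/right hindpaw.
#' @export
tonicgl_markers <- c("nose", "neck", "chest", "anus", "tail_tip",
                     "l_forepaw", "r_forepaw", "l_hindpaw", "r_hindpaw")

#' 3D skeleton time series
#'
#' Container for 9-marker, 20-Hz pose trajectories in an open-field
#' arena (origin at a floor corner, z up, cm units).
#'
#' @param t Time, s, uniform at 20 Hz.
#' @param pos Numeric array `[frame, marker, coord]` with marker order
#'   [tonicgl_markers] and coords x, y, z in cm.
#' @param arena_cm Arena dimensions `c(x, y, z)`, cm.
#' @return Object of class `skeleton_3d`.
#' @export
skeleton_3d <- function(t, pos, arena_cm = c(20, 20, 30)) {
  stopifnot(length(dim(pos)) == 3, dim(pos)[1] == length(t),
            dim(pos)[2] == 9, dim(pos)[3] == 3)
  dt <- diff(t)
  if (length(dt) > 0 &&
      (max(dt) - min(dt)) > 1e-6 * mean(dt))
    stop("skeleton must be uniformly sampled", call. = FALSE)
  if (length(dt) > 0 && abs(mean(dt) - 0.05) > 1e-6)
    stop("skeleton must be sampled at 20 Hz", call. = FALSE)
  if (!all(is.finite(pos)))
    stop("marker positions must be finite", call. = FALSE)
  dimnames(pos) <- list(NULL, tonicgl_markers, c("x", "y", "z"))
  structure(list(t = as.numeric(t), pos = pos,
                 arena_cm = as.numeric(arena_cm)),
            class = "skeleton_3d")
}

#' @export
print.skeleton_3d <- function(x, ...) {
  cat(sprintf("9-marker skeleton: %d frames at 20 Hz (%.1f s), arena %g x %g x %g cm\n",
              length(x$t), length(x$t) / 20, x$arena_cm[1], x$arena_cm[2],
              x$arena_cm[3]))
  invisible(x)
}

#' Ground truth for a synthetic gait recording
#'
#' @param stride_frequency_Hz Stride (limb oscillation) frequency, Hz.
#' @param lr_phase_mix Left-right phase structure in `[0, 1]`: 0 is pure
#'   antiphase (alternating gait), 1 pure in-phase (hopping-like). May be
#'   a vector with one value per turning segment.
#' @param turning_profile Signed heading angular velocity per segment,
#'   deg/s; the recording is split into `length(turning_profile)` equal
#'   segments.
#' @param rear_episodes List of `c(start, end)` intervals, s,
#'   non-overlapping, during which the forepaws (and head) are elevated.
#' @param marker_noise_sd Isotropic Gaussian marker noise SD, cm.
#' @param stride_jitter Relative SD of stride-cycle durations.
#' @param placement_noise_sd SD of the smooth per-stride lateral hindpaw
#'   placement offsets, cm.
#' @param speed_cm_s Trunk translation speed, cm/s.
#' @return Object of class `gait_ground_truth`.
#' @export
gait_ground_truth <- function(stride_frequency_Hz = 2.5, lr_phase_mix = 0,
                              turning_profile = 0,
                              rear_episodes = list(),
                              marker_noise_sd = 0.05,
                              stride_jitter = 0,
                              placement_noise_sd = 0,
                              speed_cm_s = 6) {
  stopifnot(stride_frequency_Hz > 0,
            all(lr_phase_mix >= 0), all(lr_phase_mix <= 1),
            marker_noise_sd >= 0, stride_jitter >= 0,
            placement_noise_sd >= 0, speed_cm_s >= 0)
  if (length(rear_episodes) > 0) {
    m <- do.call(rbind, rear_episodes)
    if (any(m[, 2] <= m[, 1]))
      stop("rear episodes must have end > start", call. = FALSE)
    o <- order(m[, 1])
    if (any(m[o, 1][-1] < m[o, 2][-nrow(m)]))
      stop("rear episodes must not overlap", call. = FALSE)
  }
  structure(list(stride_frequency_Hz = stride_frequency_Hz,
                 lr_phase_mix = lr_phase_mix,
                 turning_profile = as.numeric(turning_profile),
                 rear_episodes = rear_episodes,
                 marker_noise_sd = marker_noise_sd,
                 stride_jitter = stride_jitter,
                 placement_noise_sd = placement_noise_sd,
                 speed_cm_s = speed_cm_s),
            class = "gait_ground_truth")
}

#' Generate a synthetic 9-marker gait recording
#'
#' Renders an open-field recording at 20 Hz: the trunk follows a smooth
#' 2D walk whose heading integrates the prescribed turning profile
#' (reflecting at the arena walls), and the paws oscillate at the stride
#' frequency with the prescribed left-right phase structure.
#'
#' The per-cycle limb-angle waveform is a von Mises-type bump,
#' \eqn{\exp(\kappa(\cos\phi - 1))}: the angle changes quickly during the
#' swing phase and is nearly still during stance, so the *unsigned*
#' angular speeds of two limbs in antiphase are negatively correlated,
#' as in real alternating gait. The right-side waveform is the mixture
#' `(1 - mix) * antiphase + mix * in-phase`; diagonal limbs move in
#' phase (trot-like coupling). Paw height rises during the swing, so its
#' spectral peak sits at the stride frequency. During rear episodes both
#' forepaws (and the head) are smoothly elevated several cm above the
#' hindpaws.
#'
#' @param truth A [gait_ground_truth()].
#' @param duration Duration, s (<= 600; rear episodes must fit inside).
#' @param seed Integer seed.
#' @param kappa Sharpness of the swing bump.
#' @return List with `skeleton` (a [skeleton_3d()]) and `truth`
#'   (unchanged), plus `phase` (the left-side stride phase, rad).
#' @export
gen_skeleton <- function(truth, duration, seed = 1, kappa = 3) {
  stopifnot(inherits(truth, "gait_ground_truth"), duration > 0,
            duration <= 600)
  if (length(truth$rear_episodes) > 0 &&
      max(vapply(truth$rear_episodes, max, numeric(1))) > duration)
    stop("rear episodes must lie within the recording", call. = FALSE)
  set.seed(seed)
  fps <- 20
  n <- round(duration * fps)
  t <- (seq_len(n) - 1) / fps
  arena <- c(20, 20, 30)

  # ---- stride phase with optional per-cycle duration jitter ----
  f <- truth$stride_frequency_Hz
  if (truth$stride_jitter > 0) {
    n_cyc <- ceiling(duration * f * 2) + 2
    T_k <- (1 / f) * pmax(0.2, 1 + stats::rnorm(n_cyc, 0,
                                                truth$stride_jitter))
    edges <- c(0, cumsum(T_k))
    cyc <- findInterval(t, edges)
    phase <- 2 * pi * ((cyc - 1) + (t - edges[cyc]) / T_k[cyc])
  } else {
    phase <- 2 * pi * f * t
  }

  # ---- heading and trunk path (billiard reflection at walls) ----
  n_seg <- length(truth$turning_profile)
  seg_of <- pmin(n_seg, floor(t / duration * n_seg) + 1L)
  omega <- truth$turning_profile[seg_of] * pi / 180  # rad/s
  theta <- cumsum(omega) / fps
  theta <- theta + stats::rnorm(1, 0, pi)  # random initial heading
  # trunk (anus) walk with smooth wall avoidance: the commanded turning
  # profile is integrated into the heading, and when the forward-
  # projected nose approaches a wall the heading is steered smoothly
  # toward the arena centre (mice curve along walls rather than bounce).
  # Limb angles are measured relative to the body axis, so steering does
  # not perturb the limb-angle waveforms.
  m_t <- 3.5     # trunk margin (lateral marker extent + noise), cm
  look <- 6.5    # forward marker extent (nose), cm
  avoid_rate <- 150 * pi / 180 / fps  # minimum avoidance turn per frame
  pos <- matrix(0, n, 2)
  p <- c(stats::runif(1, 8, 12), stats::runif(1, 8, 12))
  v <- truth$speed_cm_s / fps
  psi <- theta[1]
  avoiding <- FALSE
  head_ang <- numeric(n)
  for (i in seq_len(n)) {
    cmd <- if (i > 1) theta[i] - theta[i - 1] else 0
    proj <- p + (look + 1) * c(cos(psi), sin(psi))
    if (!avoiding &&
        (any(proj < 0.5) || any(proj > arena[1:2] - 0.5)))
      avoiding <- TRUE
    if (avoiding) {
      # steer toward the arena centre, at least as fast as the
      # commanded turning, until the body faces inward (hysteresis
      # avoids frame-by-frame chatter against the wall)
      to_c <- atan2(arena[2] / 2 - p[2], arena[1] / 2 - p[1])
      dpsi <- atan2(sin(to_c - psi), cos(to_c - psi))
      psi <- psi + sign(dpsi) * min(abs(dpsi),
                                    max(avoid_rate, abs(cmd)))
      if (abs(dpsi) < pi / 4) avoiding <- FALSE
    } else {
      psi <- psi + cmd
    }
    p_new <- p + v * c(cos(psi), sin(psi))
    # hard safety: never let the trunk leave its margin box
    p <- pmin(pmax(p_new, m_t), arena[1:2] - m_t)
    pos[i, ] <- p
    head_ang[i] <- psi
  }
  u <- cbind(cos(head_ang), sin(head_ang))       # forward
  nvec <- cbind(-sin(head_ang), cos(head_ang))   # left

  # ---- rearing envelope (smooth 0..1) ----
  rear <- numeric(n)
  for (ep in truth$rear_episodes) {
    ramp <- pmin(1, pmax(0, (t - ep[1]) / 0.3)) *
      pmin(1, pmax(0, (ep[2] - t) / 0.3))
    rear <- pmax(rear, ramp)
  }

  # ---- limb oscillation ----
  mix <- truth$lr_phase_mix
  if (length(mix) > 1) {
    mix <- rep_len(mix, n_seg)[seg_of]
  }
  # Per-cycle limb waveform: a von Mises-type swing bump — the limb
  # angle excursion is concentrated in a short swing phase and the paw
  # is nearly still in stance, so the unsigned angular speeds of two
  # antiphase limbs are negatively correlated at the native 20 Hz.
  # The right-side waveform mixes the antiphase and in-phase components
  # by lr_phase_mix (0 = alternating gait, 1 = in-phase hopping);
  # diagonal limbs are coupled in phase (trot-like).
  bump <- function(ph) exp(kappa * (cos(ph) - 1))
  w_ref <- bump(phase)
  w_anti <- bump(phase + pi)
  w_blend <- (1 - mix) * w_anti + mix * w_ref
  wv <- list(LF = w_ref, RF = w_blend, LH = w_blend, RH = w_ref)
  beta0 <- 30 * pi / 180   # resting lateral limb angle
  amp <- 35 * pi / 180     # swing amplitude
  lift <- 1.0              # paw lift during swing, cm

  # smooth per-stride lateral placement offsets for the hindpaws
  lat_off <- function() {
    if (truth$placement_noise_sd == 0) return(numeric(n))
    n_cyc <- ceiling(duration * f) + 2
    o <- stats::rnorm(n_cyc, 0, truth$placement_noise_sd)
    cyc <- pmin(n_cyc, floor(phase / (2 * pi)) + 1L)
    stats::filter(o[cyc], rep(1 / 5, 5), sides = 2) |>
      (\(x) { x[is.na(x)] <- 0; as.numeric(x) })()
  }

  # ---- assemble markers ----
  z0 <- c(nose = 3, neck = 3, chest = 2.2, anus = 2.5, tail = 1,
          paw = 0.3)
  P <- array(0, c(n, 9, 3))
  anus <- pos
  neck <- anus + 4.5 * u
  chest <- anus + 2.8 * u
  nose <- neck + 1.7 * u
  tail <- anus - 3 * u
  P[, 4, 1:2] <- anus;  P[, 4, 3] <- z0[["anus"]]
  P[, 2, 1:2] <- neck;  P[, 2, 3] <- z0[["neck"]] + 2.5 * rear
  P[, 3, 1:2] <- chest; P[, 3, 3] <- z0[["chest"]] + 1.5 * rear
  P[, 1, 1:2] <- nose;  P[, 1, 3] <- z0[["nose"]] + 4 * rear
  P[, 5, 1:2] <- tail;  P[, 5, 3] <- z0[["tail"]]

  paw <- function(attach, d, side, wvv, fore, loff = numeric(n)) {
    b <- beta0 + amp * wvv
    xy <- attach + d * (u * cos(b) + side * nvec * sin(b)) +
      nvec * loff
    z <- z0[["paw"]] + lift * wvv
    if (fore) z <- z + 5 * rear
    cbind(xy, z)
  }
  P[, 6, ] <- paw(chest, 3.0, +1, wv$LF, TRUE)              # l fore
  P[, 7, ] <- paw(chest, 3.0, -1, wv$RF, TRUE)              # r fore
  P[, 8, ] <- paw(anus, 3.5, +1, wv$LH, FALSE, lat_off())   # l hind
  P[, 9, ] <- paw(anus, 3.5, -1, wv$RH, FALSE, lat_off())   # r hind

  if (truth$marker_noise_sd > 0)
    P <- P + array(stats::rnorm(length(P), 0, truth$marker_noise_sd),
                   dim(P))

  # keep everything inside the arena
  P[, , 1] <- pmin(pmax(P[, , 1], 0.05), arena[1] - 0.05)
  P[, , 2] <- pmin(pmax(P[, , 2], 0.05), arena[2] - 0.05)
  P[, , 3] <- pmin(pmax(P[, , 3], 0.01), arena[3] - 0.05)

  list(skeleton = skeleton_3d(t, P, arena), truth = truth,
       phase = phase)
}
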