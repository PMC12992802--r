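#' Limb angles and angular speeds
#'
#' For each limb, the angle (degrees) between the limb vector and the
#' body vector, and its unsigned rate of change. Conventions: the body
#' vector runs anus to neck; forelimb vectors run chest to forepaw;
#' hindlimb vectors run anus to hindpaw. Angles are computed in 3D as
#' the arccos of the normalized dot product; angular speed uses central
#' differences at the native 20 Hz (one-sided at the ends), without
#' pre-smoothing. Frames with a zero-length vector are flagged and
#' linearly interpolated.
#'
#' @param skel A [skeleton_3d()].
#' @return Object of class `limb_angles`: list with `t`, matrices
#'   `angle_deg` and `speed_deg_s` (columns LF, RF, LH, RH) and
#'   `flagged` (interpolated frame indices).
#' @export
limb_angle_series <- function(skel) {
  stopifnot(inherits(skel, "skeleton_3d"))
  P <- skel$pos
  body <- P[, "neck", ] - P[, "anus", ]
  limbs <- list(
    LF = P[, "l_forepaw", ] - P[, "chest", ],
    RF = P[, "r_forepaw", ] - P[, "chest", ],
    LH = P[, "l_hindpaw", ] - P[, "anus", ],
    RH = P[, "r_hindpaw", ] - P[, "anus", ])
  n <- nrow(body)
  ang <- matrix(NA_real_, n, 4,
                dimnames = list(NULL, names(limbs)))
  flagged <- integer(0)
  nb <- sqrt(rowSums(body^2))
  for (k in seq_along(limbs)) {
    v <- limbs[[k]]
    nv <- sqrt(rowSums(v^2))
    ok <- nb > 1e-9 & nv > 1e-9
    cosang <- rowSums(body * v) / (nb * nv)
    a <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    a[!ok] <- NA_real_
    if (anyNA(a)) {
      flagged <- union(flagged, which(is.na(a)))
      a <- stats::approx(which(!is.na(a)), a[!is.na(a)], seq_len(n),
                         rule = 2)$y
    }
    ang[, k] <- a
  }
  dt <- 1 / 20
  speed <- apply(ang, 2, function(a) {
    d <- c(a[2] - a[1],
           (a[-(1:2)] - a[seq_len(n - 2)]) / 2,
           a[n] - a[n - 1])
    abs(d) / dt
  })
  structure(list(t = skel$t, angle_deg = ang, speed_deg_s = speed,
                 flagged = sort(flagged)),
            class = "limb_angles")
}

#' @export
print.limb_angles <- function(x, ...) {
  cat(sprintf("Limb angles: %d frames, mean angles %s deg\n",
              nrow(x$angle_deg),
              paste(sprintf("%s=%.0f", colnames(x$angle_deg),
                            colMeans(x$angle_deg)), collapse = " ")))
  invisible(x)
}

#' Rapid whole-body motion mask
#'
#' A frame belongs to rapid whole-body motion iff (i) the anus-marker
#' speed exceeds `speed_threshold` and (ii) each forepaw is no higher
#' than the per-frame hindpaw reference (the higher of the two hindpaw
#' z) plus `height_multiplier` times the recording-wide SD of the
#' left-right hindpaw vertical distance. Criterion (ii) removes rearing
#' frames, where both forepaws rise together.
#'
#' @param skel A [skeleton_3d()].
#' @param speed_threshold Anus speed threshold, cm/s.
#' @param height_multiplier Multiplier of the hindpaw z-difference SD
#'   (2.576 bounds 99% of a normal distribution).
#' @return Object of class `motion_mask`: list with logical `mask`
#'   per frame and the `criteria` record.
#' @export
rapid_motion_mask <- function(skel, speed_threshold = 2,
                              height_multiplier = 2.576) {
  stopifnot(inherits(skel, "skeleton_3d"))
  P <- skel$pos
  n <- dim(P)[1]
  dt <- 1 / 20
  anus <- P[, "anus", ]
  vel <- rbind(anus[2, ] - anus[1, ],
               (anus[-(1:2), , drop = FALSE] -
                  anus[seq_len(n - 2), , drop = FALSE]) / 2,
               anus[n, ] - anus[n - 1, ]) / dt
  speed <- sqrt(rowSums(vel^2))
  zl <- P[, "l_hindpaw", "z"]; zr <- P[, "r_hindpaw", "z"]
  ref <- pmax(zl, zr)
  lim <- height_multiplier * stats::sd(zl - zr)
  ok_height <- P[, "l_forepaw", "z"] <= ref + lim &
    P[, "r_forepaw", "z"] <= ref + lim
  structure(list(mask = speed > speed_threshold & ok_height,
                 anus_speed = speed,
                 criteria = list(speed_threshold = speed_threshold,
                                 height_multiplier = height_multiplier,
                                 height_limit = lim)),
            class = "motion_mask")
}

#' Interlimb angular-speed correlation matrix
#'
#' Pearson correlations of the four limb angular speeds (LF, RF, LH,
#' RH) over the frames of a rapid-motion mask.
#'
#' @param angles A [limb_angle_series()].
#' @param mask A [rapid_motion_mask()] (or a logical vector per frame).
#' @param min_frames Minimum masked frames required.
#' @return Object of class `limb_correlations`: the symmetric 4x4
#'   matrix `r` with unit diagonal, and `n_frames`.
#' @export
limb_speed_correlations <- function(angles, mask, min_frames = 50) {
  stopifnot(inherits(angles, "limb_angles"))
  m <- if (inherits(mask, "motion_mask")) mask$mask else as.logical(mask)
  stopifnot(length(m) == nrow(angles$speed_deg_s))
  if (sum(m) < min_frames)
    stop("insufficient rapid-motion frames: ", sum(m), " < ",
         min_frames, call. = FALSE)
  r <- stats::cor(angles$speed_deg_s[m, , drop = FALSE])
  structure(list(r = r, n_frames = sum(m)),
            class = "limb_correlations")
}

#' @export
print.limb_correlations <- function(x, ...) {
  cat(sprintf("Interlimb angular-speed correlations (%d frames)\n",
              x$n_frames))
  print(round(x$r, 3))
  invisible(x)
}

# heading azimuth (rad) of the horizontal anus->neck vector, and its
# unsigned angular speed (deg/s) by central differences
.heading_series <- function(skel) {
  P <- skel$pos
  v <- P[, "neck", 1:2] - P[, "anus", 1:2]
  az <- atan2(v[, 2], v[, 1])
  n <- length(az)
  d <- diff(az)
  d <- atan2(sin(d), cos(d))  # unwrap steps to (-pi, pi]
  dt <- 1 / 20
  cen <- c(d[1], (d[-1] + d[-length(d)]) / 2, d[length(d)]) / dt
  list(azimuth = az, turn_deg_s = abs(cen) * 180 / pi,
       turn_signed_deg_s = cen * 180 / pi)
}

#' Segment a recording into homogeneous movement bouts
#'
#' Computes multiscale sliding-window features (translational speed,
#' turning speed, mean paw height, and stride-band power, each over
#' 0.5-, 1- and 2-s windows at a 0.25-s stride), finds change points by
#' binary segmentation on the standardized feature matrix (splits are
#' kept while they reduce the within-segment sum of squares by more than
#' a BIC-style penalty), and clusters the segment-mean features with
#' k-means.
#'
#' @param skel A [skeleton_3d()], at least 30 s long.
#' @param k Number of k-means clusters (reduced if there are fewer
#'   segments).
#' @param stride_s Feature stride, s.
#' @param scales_s Feature window lengths, s.
#' @param min_seg_s Minimum segment length, s.
#' @param seed Integer seed for k-means.
#' @return Object of class `movement_segments`: data.frame `segments`
#'   (`start_s`, `end_s`, `cluster`), per-frame `frame_cluster`, the
#'   change points `changepoints_s` and the feature matrix.
#' @export
segment_movements <- function(skel, k = 8, stride_s = 0.25,
                              scales_s = c(0.5, 1, 2), min_seg_s = 2,
                              penalty_mult = 4, seed = 1) {
  stopifnot(inherits(skel, "skeleton_3d"))
  dur <- length(skel$t) / 20
  if (dur < 30)
    stop("recording must be at least 30 s for segmentation",
         call. = FALSE)
  P <- skel$pos
  hd <- .heading_series(skel)
  anus <- P[, "anus", ]
  n <- dim(P)[1]
  sp <- c(0, sqrt(rowSums(diff(anus)^2))) * 20
  pawz <- rowMeans(P[, 6:9, "z"])
  centers <- seq(1, n, by = round(stride_s * 20))
  feat <- NULL
  for (w in scales_s) {
    half <- max(1L, round(w * 20 / 2))
    fmat <- t(vapply(centers, function(c0) {
      idx <- max(1L, c0 - half):min(n, c0 + half)
      z <- pawz[idx]
      # stride-band power: variance of the detrended paw height
      c(mean(sp[idx]), mean(hd$turn_deg_s[idx]), mean(z),
        stats::var(z - mean(z)))
    }, numeric(4)))
    feat <- cbind(feat, fmat)
  }
  sds <- apply(feat, 2, stats::sd)
  sds[sds == 0] <- 1
  Z <- sweep(sweep(feat, 2, colMeans(feat)), 2, sds, "/")

  min_len <- max(2L, round(min_seg_s / stride_s))
  cps <- .binary_segment(Z, min_len, penalty_mult)
  bounds <- c(0, cps, nrow(Z))
  n_seg <- length(bounds) - 1
  seg_means <- t(vapply(seq_len(n_seg), function(s) {
    colMeans(Z[(bounds[s] + 1):bounds[s + 1], , drop = FALSE])
  }, numeric(ncol(Z))))
  if (n_seg <= k) {
    # no more segments than clusters: each segment is its own cluster
    cl <- seq_len(n_seg)
  } else {
    set.seed(seed)
    cl <- stats::kmeans(seg_means, centers = k, nstart = 10,
                        iter.max = 50)$cluster
  }

  cp_times <- cps * stride_s
  seg_df <- data.frame(start_s = bounds[-length(bounds)] * stride_s,
                       end_s = pmin(dur, bounds[-1] * stride_s),
                       cluster = cl)
  frame_seg <- findInterval(skel$t, seg_df$start_s,
                            rightmost.closed = FALSE)
  frame_seg <- pmin(pmax(frame_seg, 1L), n_seg)
  structure(list(segments = seg_df, frame_segment = frame_seg,
                 frame_cluster = cl[frame_seg],
                 changepoints_s = cp_times, features = Z,
                 stride_s = stride_s),
            class = "movement_segments")
}

# binary segmentation on rows of Z: recursively accept the best split
# while it reduces the within-segment SSE by more than a BIC-style
# penalty sigma2 * d * log(n_total)
.binary_segment <- function(Z, min_len, penalty_mult = 2) {
  n_tot <- nrow(Z)
  d <- ncol(Z)
  sigma2 <- mean(apply(Z, 2, function(x) {
    if (length(x) < 2) return(0)
    stats::var(diff(x)) / 2
  }))
  penalty <- max(sigma2, 1e-12) * d * log(n_tot) * penalty_mult
  rec <- function(lo, hi) {
    n <- hi - lo + 1
    if (n < 2 * min_len) return(integer(0))
    X <- Z[lo:hi, , drop = FALSE]
    cs <- apply(X, 2, cumsum)
    tot <- cs[n, ]
    sse_full <- sum(X^2) - sum(tot^2) / n
    best_gain <- -Inf; best_s <- NA_integer_
    for (s in min_len:(n - min_len)) {
      left <- cs[s, ]
      right <- tot - left
      sse_split <- sum(X^2) - sum(left^2) / s - sum(right^2) / (n - s)
      gain <- sse_full - sse_split
      if (gain > best_gain) { best_gain <- gain; best_s <- s }
    }
    if (!is.na(best_s) && best_gain > penalty) {
      cp <- lo + best_s - 1
      return(c(rec(lo, cp), cp, rec(cp + 1, hi)))
    }
    integer(0)
  }
  rec(1, n_tot)
}

#' @export
print.movement_segments <- function(x, ...) {
  cat(sprintf("Movement segmentation: %d segment(s), %d change point(s), %d cluster(s)\n",
              nrow(x$segments), length(x$changepoints_s),
              length(unique(x$segments$cluster))))
  invisible(x)
}

#' Probability of positive limb correlation versus turning speed
#'
#' For each movement segment, computes the Pearson correlation of a limb
#' pair's angular speeds over the segment's rapid-motion frames and the
#' segment's mean unsigned turning speed (heading = horizontal
#' anus-to-neck azimuth). Segments are binned by turning speed
#' (quantile bins) and the per-bin probability of a positive correlation
#' is reported with a bootstrap s.e.m.
#'
#' @param skel A [skeleton_3d()].
#' @param segments A [segment_movements()] result.
#' @param limb_pair Two of `"LF"`, `"RF"`, `"LH"`, `"RH"`.
#' @param n_bins Number of turning-speed bins.
#' @param min_frames Minimum rapid-motion frames for a segment to count.
#' @param n_boot Bootstrap iterations for the s.e.m.
#' @param seed Integer seed for the bootstrap.
#' @return Object of class `corr_vs_turning`: data.frame `curve` with
#'   `turn_lo`, `turn_hi`, `turn_mid`, `p_positive`, `sem`, `n_segments`
#'   (empty bins flagged by `n_segments = 0` and `NA` probability), and
#'   the per-segment table `segments`.
#' @export
positive_corr_vs_turning <- function(skel, segments,
                                     limb_pair = c("LF", "RF"),
                                     n_bins = 4, min_frames = 20,
                                     n_boot = 1000, seed = 1) {
  stopifnot(inherits(skel, "skeleton_3d"),
            inherits(segments, "movement_segments"),
            length(limb_pair) == 2,
            all(limb_pair %in% c("LF", "RF", "LH", "RH")))
  ang <- limb_angle_series(skel)
  mk <- rapid_motion_mask(skel)$mask
  hd <- .heading_series(skel)
  seg_df <- segments$segments
  per_seg <- lapply(seq_len(nrow(seg_df)), function(s) {
    fr <- which(segments$frame_segment == s)
    use <- fr[mk[fr]]
    if (length(use) < min_frames) return(NULL)
    sp <- ang$speed_deg_s[use, limb_pair]
    if (any(apply(sp, 2, stats::sd) == 0)) return(NULL)
    data.frame(segment = s,
               corr = stats::cor(sp[, 1], sp[, 2]),
               turn = mean(hd$turn_deg_s[fr]))
  })
  seg_tab <- do.call(rbind, per_seg)
  if (is.null(seg_tab) || nrow(seg_tab) < 10)
    stop("need at least 10 usable segments, got ",
         if (is.null(seg_tab)) 0 else nrow(seg_tab), call. = FALSE)
  br <- unique(stats::quantile(seg_tab$turn,
                               probs = seq(0, 1, length.out = n_bins + 1)))
  if (length(br) < 2) br <- range(seg_tab$turn) + c(-1e-9, 1e-9)
  bin <- findInterval(seg_tab$turn, br, rightmost.closed = TRUE,
                      all.inside = TRUE)
  curve <- do.call(rbind, lapply(seq_len(length(br) - 1), function(b) {
    inb <- seg_tab$corr[bin == b]
    if (length(inb) == 0)
      return(data.frame(turn_lo = br[b], turn_hi = br[b + 1],
                        turn_mid = (br[b] + br[b + 1]) / 2,
                        p_positive = NA_real_, sem = NA_real_,
                        n_segments = 0L))
    pos <- as.numeric(inb > 0)
    sem <- if (length(pos) >= 2)
      bootstrap_sem(pos, mean, n_iter = n_boot, seed = seed)$sem
    else NA_real_
    data.frame(turn_lo = br[b], turn_hi = br[b + 1],
               turn_mid = (br[b] + br[b + 1]) / 2,
               p_positive = mean(pos), sem = sem,
               n_segments = length(pos))
  }))
  structure(list(curve = curve, segments = seg_tab,
                 limb_pair = limb_pair),
            class = "corr_vs_turning")
}

#' @export
print.corr_vs_turning <- function(x, ...) {
  cat(sprintf("P(positive %s-%s correlation) by turning speed:\n",
              x$limb_pair[1], x$limb_pair[2]))
  print(round(x$curve[, c("turn_mid", "p_positive", "sem",
                          "n_segments")], 3))
  invisible(x)
}

#' Classical gait metrics
#'
#' Stride events are detected as peaks of the hindpaw forward velocity
#' in the body frame (paw position relative to the anus, projected on
#' the heading, differentiated centrally — this is invariant to turning
#' and wall encounters); from them the function derives:
#' \itemize{
#'   \item `stride_time_cv`: SD/mean of inter-stride intervals;
#'   \item `step_width_cv`: SD/mean of the lateral hindpaw separation at
#'     stance (velocity minima between strides);
#'   \item `ataxia_index`: mean unsigned scatter of the lateral hindpaw
#'     placement (distance from the body-axis line, centred on each
#'     side's median track width), normalized by body length — regular
#'     gait re-places each paw at a reproducible lateral offset, so the
#'     scatter, not the offset itself, indexes placement irregularity;
#'   \item `interlimb_phase_variance`: circular variance of the
#'     left-forepaw to right-hindpaw phase lag across strides.
#' }
#' These metric definitions follow common mouse-gait conventions and are
#' fixed by this package (documented here, validated against the
#' synthetic generator).
#'
#' @param skel A [skeleton_3d()].
#' @param min_strides Minimum detected strides required.
#' @return Object of class `gait_metrics`: list with the four metrics
#'   and `n_strides`.
#' @export
gait_metrics <- function(skel, min_strides = 20) {
  stopifnot(inherits(skel, "skeleton_3d"))
  P <- skel$pos
  n <- dim(P)[1]
  dt <- 1 / 20
  hd <- .heading_series(skel)
  u <- cbind(cos(hd$azimuth), sin(hd$azimuth))

  fwd_vel <- function(marker) {
    # forward coordinate in the body frame, then central differences
    x <- rowSums((P[, marker, 1:2] - P[, "anus", 1:2]) * u)
    c(x[2] - x[1], (x[-(1:2)] - x[seq_len(n - 2)]) / 2,
      x[n] - x[n - 1]) / dt
  }
  fv_lh <- fwd_vel("l_hindpaw")
  pk_l <- .find_peaks(fv_lh, min_dist = 3)
  if (length(pk_l) < min_strides)
    stop("insufficient strides detected: ", length(pk_l), " < ",
         min_strides, call. = FALSE)
  stride_t <- diff(skel$t[pk_l])
  stride_time_cv <- stats::sd(stride_t) / mean(stride_t)

  # stance frames: forward-velocity minima between consecutive strides
  stance <- vapply(seq_len(length(pk_l) - 1), function(i) {
    idx <- pk_l[i]:pk_l[i + 1]
    idx[which.min(fv_lh[idx])]
  }, integer(1))
  sep <- vapply(stance, function(i) {
    d <- P[i, "r_hindpaw", 1:2] - P[i, "l_hindpaw", 1:2]
    abs(sum(d * c(-sin(hd$azimuth[i]), cos(hd$azimuth[i]))))
  }, numeric(1))
  step_width_cv <- stats::sd(sep) / mean(sep)

  body_len <- mean(sqrt(rowSums((P[, "neck", ] - P[, "anus", ])^2)))
  lat_scatter <- function(marker, frames) {
    lat <- vapply(frames, function(i) {
      d <- P[i, marker, 1:2] - P[i, "anus", 1:2]
      sum(d * c(-sin(hd$azimuth[i]), cos(hd$azimuth[i])))
    }, numeric(1))
    abs(lat - stats::median(lat))
  }
  ataxia_index <- mean(c(lat_scatter("l_hindpaw", stance),
                         lat_scatter("r_hindpaw", stance))) / body_len

  pk_rh <- .find_peaks(fwd_vel("r_hindpaw"), min_dist = 3)
  pk_lf <- .find_peaks(fwd_vel("l_forepaw") , min_dist = 3)
  period <- mean(stride_t)
  lags <- vapply(skel$t[pk_lf], function(tt) {
    if (length(pk_rh) == 0) return(NA_real_)
    (min(abs(skel$t[pk_rh] - tt)) / period) * 2 * pi
  }, numeric(1))
  lags <- lags[is.finite(lags)]
  phase_var <- if (length(lags) >= 2)
    1 - sqrt(mean(cos(lags))^2 + mean(sin(lags))^2)
  else NA_real_

  structure(list(stride_time_cv = stride_time_cv,
                 step_width_cv = step_width_cv,
                 ataxia_index = ataxia_index,
                 interlimb_phase_variance = phase_var,
                 n_strides = length(pk_l)),
            class = "gait_metrics")
}

# local maxima above mean + 0.25 sd, separated by at least min_dist
# samples (largest peak kept per cluster)
.find_peaks <- function(x, min_dist = 3) {
  n <- length(x)
  if (n < 3) return(integer(0))
  thr <- mean(x) + 0.25 * stats::sd(x)
  cand <- which(x[2:(n - 1)] >= x[1:(n - 2)] &
                  x[2:(n - 1)] >= x[3:n]) + 1L
  cand <- cand[x[cand] > thr]
  if (length(cand) == 0) return(integer(0))
  keep <- integer(0)
  last <- -Inf
  for (i in cand) {
    if (i - last >= min_dist) {
      keep <- c(keep, i)
      last <- i
    } else if (x[i] > x[keep[length(keep)]]) {
      keep[length(keep)] <- i
      last <- i
    }
  }
  keep
}

#' @export
print.gait_metrics <- function(x, ...) {
  cat(sprintf(paste0("Gait metrics (%d strides): stride-time CV %.3f, ",
                     "step-width CV %.3f, ataxia index %.3f, ",
                     "interlimb phase variance %.3f\n"),
              x$n_strides, x$stride_time_cv, x$step_width_cv,
              x$ataxia_index, x$interlimb_phase_variance))
  invisible(x)
}
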