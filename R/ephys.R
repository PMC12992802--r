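#' Holding-current trace recording
#'
#' Container for a voltage-clamp holding-current recording with annotated
#' drug-application events: uniformly sampled time (s), current (pA,
#' inward negative) and an ordered event table.
#'
#' @param t Time, s; strictly increasing, uniform step (within 1 ppm).
#' @param I Holding current, pA; same length as `t`.
#' @param events `data.frame` with columns `label` (unique) and `time`
#'   (sorted), or `NULL`.
#' @param meta Optional named list of condition labels (age, genotype,
#'   protocol).
#' @return Object of class `trace_recording` with fields `t`, `I`,
#'   `events`, `meta` and `rate_Hz`.
#' @export
trace_recording <- function(t, I, events = NULL, meta = list()) {
  stopifnot(is.numeric(t), is.numeric(I), length(t) == length(I),
            length(t) >= 2)
  dt <- diff(t)
  if (any(dt <= 0))
    stop("t must be strictly increasing", call. = FALSE)
  if ((max(dt) - min(dt)) > 1e-6 * mean(dt))
    stop("t must be uniformly sampled within 1 ppm", call. = FALSE)
  if (is.null(events))
    events <- data.frame(label = character(0), time = numeric(0))
  stopifnot(all(c("label", "time") %in% names(events)))
  if (is.unsorted(events$time))
    stop("events must be sorted by time", call. = FALSE)
  if (anyDuplicated(events$label))
    stop("event labels must be unique", call. = FALSE)
  structure(list(t = as.numeric(t), I = as.numeric(I), events = events,
                 meta = meta, rate_Hz = 1 / mean(dt)),
            class = "trace_recording")
}

#' @export
print.trace_recording <- function(x, ...) {
  cat(sprintf("Holding-current trace: %.1f s at %.0f Hz, %d drug event(s)\n",
              max(x$t), x$rate_Hz, nrow(x$events)))
  if (nrow(x$events) > 0)
    cat(sprintf("  %s at %.1f s\n", x$events$label, x$events$time),
        sep = "")
  invisible(x)
}

# Baseline level of a window of current samples: mode of a Gaussian
# fitted to the all-point histogram. IPSC transients populate one tail
# only, so the fit is restricted to bins above 20% of the peak count;
# falls back to the kernel-density mode if the fit fails.
.baseline_mode <- function(x) {
  stopifnot(length(x) >= 100)
  if (diff(range(x)) < 1e-9) return(mean(x))
  nb <- max(30, grDevices::nclass.FD(x))
  h <- graphics::hist(x, breaks = nb, plot = FALSE)
  mids <- h$mids
  cnt <- h$counts
  keep <- cnt >= 0.2 * max(cnt)
  df <- data.frame(m = mids[keep], c = cnt[keep])
  mu0 <- mids[which.max(cnt)]
  s0 <- max(stats::mad(x), diff(range(mids)) / 20)
  fit <- tryCatch(
    suppressWarnings(
      stats::nls(c ~ A * exp(-(m - mu)^2 / (2 * s^2)), data = df,
                 start = list(A = max(cnt), mu = mu0, s = s0),
                 control = stats::nls.control(warnOnly = TRUE))),
    error = function(e) NULL)
  if (!is.null(fit)) {
    mu <- stats::coef(fit)[["mu"]]
    if (is.finite(mu) && mu >= min(mids) && mu <= max(mids)) return(mu)
  }
  d <- tryCatch(stats::density(x), error = function(e) NULL)
  if (is.null(d)) stats::median(x) else d$x[which.max(d$y)]
}

# Window bounds [t0, t1] for the baseline of a transition side, with
# settling-margin checks against neighbouring events.
.window_samples <- function(trace, t0, t1, what) {
  if (t0 < trace$t[1] - 1e-9 || t1 > trace$t[length(trace$t)] + 1e-9)
    stop(what, " window [", round(t0, 1), ", ", round(t1, 1),
         "] extends past the trace", call. = FALSE)
  idx <- which(trace$t >= t0 & trace$t <= t1)
  if (length(idx) < 100)
    stop(what, " window holds too few samples", call. = FALSE)
  trace$I[idx]
}

#' Drug-induced baseline shift
#'
#' Measures the baseline shift of the holding current across one drug
#' transition, e.g. the tonic GABA-A current as the shift after gabazine.
#' The baseline on each side is the mode of a Gaussian fitted to the
#' all-point histogram of a measurement window, which is robust to the
#' inward IPSC transients riding on the baseline.
#'
#' The pre window is the `pre_window` seconds ending at the transition's
#' event; the post window is `post_window` seconds starting
#' `settle` seconds after it. Windows that overlap another event's
#' settling period or run past the trace raise an error.
#'
#' @param trace A [trace_recording()].
#' @param transition Length-2 character vector `c(from, to)` or a single
#'   string `"from->to"`; `from` is `"base"` or a prior event label, `to`
#'   an event label.
#' @param pre_window,post_window Window lengths, s.
#' @param settle Settling margin after each event, s.
#' @return Baseline shift \eqn{\Delta I} = post - pre, pA. A GABA-A
#'   blocker removing an inward tonic current yields a positive shift.
#' @examples
#' g <- gen_tonic_trace(c("TTX", "GBZ"),
#'   trace_ground_truth(-200, c("base->TTX" = 5, "TTX->GBZ" = 5)),
#'   duration = 450, rate = 100, seed = 1)
#' drug_shift(g$trace, c("base", "TTX"))   # 5
#' @export
drug_shift <- function(trace, transition, pre_window = 30,
                       post_window = 30, settle = 60) {
  stopifnot(inherits(trace, "trace_recording"))
  if (length(transition) == 1)
    transition <- strsplit(transition, "->", fixed = TRUE)[[1]]
  stopifnot(length(transition) == 2)
  ev <- trace$events
  to_i <- match(transition[2], ev$label)
  if (is.na(to_i))
    stop("no event labelled '", transition[2], "' in trace", call. = FALSE)
  t_ev <- ev$time[to_i]

  pre0 <- t_ev - pre_window
  if (identical(transition[1], "base")) {
    if (to_i > 1)
      stop("transition names 'base' but '", ev$label[to_i - 1],
           "' precedes '", transition[2], "'", call. = FALSE)
  } else {
    from_i <- match(transition[1], ev$label)
    if (is.na(from_i) || from_i != to_i - 1)
      stop("'", transition[1], "' does not immediately precede '",
           transition[2], "'", call. = FALSE)
    if (pre0 < ev$time[from_i] + settle)
      stop("pre window overlaps the settling period after '",
           transition[1], "'", call. = FALSE)
  }
  post0 <- t_ev + settle
  post1 <- post0 + post_window
  if (to_i < nrow(ev) && post1 > ev$time[to_i + 1])
    stop("post window overlaps the next event '", ev$label[to_i + 1],
         "'", call. = FALSE)

  pre <- .baseline_mode(.window_samples(trace, pre0, t_ev, "pre"))
  post <- .baseline_mode(.window_samples(trace, post0, post1, "post"))
  post - pre
}

#' Decompose a tonic current into pharmacological components
#'
#' Applies [drug_shift()] to each consecutive transition of a recording
#' protocol and books the results as TTX-sensitive (spillover, i.e.
#' action-potential-dependent) and TTX-insensitive (nonsynaptic)
#' components of the total tonic GABA-A current. The components sum to
#' the total exactly, by construction.
#'
#' @param trace A [trace_recording()] containing the protocol's events in
#'   order.
#' @param protocol `"ttx-gbz"` (events TTX then GBZ; total tonic measured
#'   from the drug-free baseline) or `"npa-ttx-gbz"` (GAT blockade first;
#'   total tonic measured from the NPA level).
#' @inheritParams drug_shift
#' @return Object of class `tonic_decomposition`: list with `shifts`
#'   (named per transition), `total_tonic_pA`, `ttx_sensitive_pA`,
#'   `ttx_insensitive_pA`, `ttx_sensitive_fraction` (`NA` and flagged
#'   `fraction_undefined` when the total is not positive) and
#'   `negative_components` (labels of negative shifts, reported as-is,
#'   not clipped).
#' @export
decompose_tonic <- function(trace, protocol = c("ttx-gbz", "npa-ttx-gbz"),
                            pre_window = 30, post_window = 30,
                            settle = 60) {
  protocol <- match.arg(protocol)
  drugs <- switch(protocol, "ttx-gbz" = c("TTX", "GBZ"),
                  "npa-ttx-gbz" = c("NPA", "TTX", "GBZ"))
  if (!identical(trace$events$label, drugs))
    stop("trace events (", paste(trace$events$label, collapse = ", "),
         ") do not match protocol ", protocol, call. = FALSE)
  froms <- c("base", drugs[-length(drugs)])
  labels <- paste0(froms, "->", drugs)
  shifts <- vapply(seq_along(drugs), function(k)
    drug_shift(trace, c(froms[k], drugs[k]), pre_window, post_window,
               settle), numeric(1))
  names(shifts) <- labels

  # components are measured from the protocol's reference level: the
  # drug-free base for ttx-gbz, the NPA level for npa-ttx-gbz
  ttx_s <- shifts[[paste0(froms[match("TTX", drugs)], "->TTX")]]
  ttx_i <- shifts[["TTX->GBZ"]]
  total <- ttx_s + ttx_i
  frac <- if (total > 0) ttx_s / total else NA_real_
  structure(list(shifts = shifts,
                 total_tonic_pA = total,
                 ttx_sensitive_pA = ttx_s,
                 ttx_insensitive_pA = ttx_i,
                 ttx_sensitive_fraction = frac,
                 fraction_undefined = !(total > 0),
                 negative_components = names(shifts)[shifts < 0],
                 protocol = protocol),
            class = "tonic_decomposition")
}

#' @export
print.tonic_decomposition <- function(x, ...) {
  cat(sprintf("Tonic GABA-A decomposition (%s)\n", x$protocol))
  for (nm in names(x$shifts))
    cat(sprintf("  %-12s %+7.2f pA\n", nm, x$shifts[[nm]]))
  cat(sprintf("  total tonic      %7.2f pA\n", x$total_tonic_pA))
  cat(sprintf("  TTX-sensitive    %7.2f pA  (fraction %s)\n",
              x$ttx_sensitive_pA,
              if (x$fraction_undefined) "undefined"
              else sprintf("%.3f", x$ttx_sensitive_fraction)))
  cat(sprintf("  TTX-insensitive  %7.2f pA\n", x$ttx_insensitive_pA))
  if (length(x$negative_components) > 0)
    cat("  note: negative component(s): ",
        paste(x$negative_components, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Detect spontaneous IPSCs in a holding-current trace
#'
#' Matched-filter event detection: the trace is detrended with a running
#' median, cross-correlated with the canonical IPSC template
#' (instantaneous rise, single-exponential decay), and thresholded at
#' `k` robust SDs (MAD) of the filtered signal. Detections closer than
#' a refractory margin are merged.
#'
#' @param trace A [trace_recording()].
#' @param window Length-2 numeric `c(t0, t1)`, s; must precede GABA-A
#'   blockade (a `GBZ` event). Defaults to the whole pre-GBZ span.
#' @param tau_ms Template decay time constant, ms.
#' @param k Detection threshold in MADs of the filtered signal.
#' @param refractory_ms Merge detections closer than this, ms.
#' @return Object of class `ipsc_events`: list with `times` (s),
#'   `amplitudes` (pA, positive magnitudes), `frequency_Hz` and
#'   `mean_amplitude_pA`.
#' @export
detect_ipscs <- function(trace, window = NULL, tau_ms = 10, k = 4,
                         refractory_ms = 5) {
  stopifnot(inherits(trace, "trace_recording"))
  gbz <- match("GBZ", trace$events$label)
  t_end <- if (is.na(gbz)) max(trace$t) else trace$events$time[gbz]
  if (is.null(window)) window <- c(trace$t[1], t_end)
  stopifnot(length(window) == 2, window[1] < window[2])
  if (window[2] > t_end + 1e-9)
    stop("detection window extends past GABA-A blockade", call. = FALSE)
  idx <- which(trace$t >= window[1] & trace$t <= window[2])
  if (length(idx) < 50)
    stop("detection window holds too few samples", call. = FALSE)
  rate <- trace$rate_Hz
  x <- trace$I[idx]
  tt <- trace$t[idx]

  # detrend: remove baseline and slow drug wash-ins, keep fast transients
  med_k <- min(length(x) - (1 - length(x) %% 2),
               2 * floor(0.25 * rate) + 1)
  s <- -(x - stats::runmed(x, med_k))  # IPSCs now positive deflections

  tau_n <- tau_ms / 1000 * rate
  tmpl <- exp(-(0:ceiling(5 * tau_n)) / tau_n)
  len <- length(tmpl)
  n_s <- length(s)
  # matched filter = cross-correlation with the template; for an event at
  # onset i the output peaks at i with value amplitude * sum(tmpl^2)
  f <- as.numeric(stats::filter(c(s, numeric(len)), rev(tmpl),
                                method = "convolution", sides = 1))
  f <- f[len:(len + n_s - 1)]
  thr <- k * stats::mad(f, na.rm = TRUE)

  times <- numeric(0); amps <- numeric(0)
  if (n_s >= 3) {
    loc_max <- which(f[2:(n_s - 1)] >= f[1:(n_s - 2)] &
                       f[2:(n_s - 1)] >= f[3:n_s]) + 1L
    pk <- loc_max[f[loc_max] > thr]
    if (length(pk) > 0) {
      # an exponential template's autocorrelation decays as
      # exp(-|dt|/tau), so every accepted event predicts a ridge in the
      # filtered signal; candidates (processed largest first) must
      # exceed the ridge of previously accepted events by the threshold
      tau_s <- tau_ms / 1000
      ord <- pk[order(f[pk], decreasing = TRUE)]
      acc_t <- numeric(0); acc_f <- numeric(0); acc_i <- integer(0)
      excess <- numeric(0)
      for (i in ord) {
        ridge <- if (length(acc_t))
          sum(acc_f * exp(-abs(tt[i] - acc_t) / tau_s)) else 0
        if (f[i] - ridge > thr) {
          acc_t <- c(acc_t, tt[i])
          acc_f <- c(acc_f, f[i] - ridge)
          acc_i <- c(acc_i, i)
          excess <- c(excess, f[i] - ridge)
        }
      }
      o <- order(acc_t)
      acc_i <- acc_i[o]; excess <- excess[o]
      # refractory merging: keep the largest of detections closer than
      # refractory_ms
      if (length(acc_i) > 0) {
        grp <- cumsum(c(TRUE, diff(tt[acc_i]) > refractory_ms / 1000))
        sel <- vapply(split(seq_along(acc_i), grp),
                      function(ii) ii[which.max(excess[ii])], integer(1))
        sel <- sort(unname(sel))
        times <- tt[acc_i[sel]]
        amps <- excess[sel] / sum(tmpl^2)
      }
    }
  }
  dur <- diff(window)
  structure(list(times = times, amplitudes = amps,
                 frequency_Hz = length(times) / dur,
                 mean_amplitude_pA = if (length(amps)) mean(amps)
                 else NA_real_,
                 window = window, threshold = thr),
            class = "ipsc_events")
}

#' @export
print.ipsc_events <- function(x, ...) {
  cat(sprintf("IPSC events: %d in [%.1f, %.1f] s (%.2f Hz, mean %.1f pA)\n",
              length(x$times), x$window[1], x$window[2], x$frequency_Hz,
              x$mean_amplitude_pA))
  invisible(x)
}

#' Linear regression of tonic-current shift on sIPSC frequency
#'
#' Ordinary least squares of baseline shift (pA) on spontaneous IPSC
#' frequency (Hz), with the coefficient of determination and a two-sided
#' p value for the zero-slope null.
#'
#' @param freq_Hz sIPSC frequencies (x), or a two-column object
#'   `(freq, shift)` if `shift_pA` is missing.
#' @param shift_pA Baseline shifts (y), pA.
#' @return List with `slope`, `intercept`, `r_squared`, `p_value`, `n`.
#' @export
fit_freq_current_regression <- function(freq_Hz, shift_pA) {
  if (missing(shift_pA)) {
    m <- as.matrix(freq_Hz)
    stopifnot(ncol(m) == 2)
    freq_Hz <- m[, 1]; shift_pA <- m[, 2]
  }
  stopifnot(length(freq_Hz) == length(shift_pA))
  ok <- is.finite(freq_Hz) & is.finite(shift_pA)
  x <- freq_Hz[ok]; y <- shift_pA[ok]
  if (length(x) < 3)
    stop("need at least 3 points", call. = FALSE)
  if (stats::sd(x) == 0)
    stop("degenerate regressor: all frequencies equal", call. = FALSE)
  fit <- stats::lm(y ~ x)
  # collinear inputs are legitimate (an exact fit), not a warning case
  sm <- suppressWarnings(summary(fit))
  slope <- unname(stats::coef(fit)[2])
  r2 <- if (stats::var(y) == 0) 0 else sm$r.squared
  p <- if (sm$sigma == 0) {
    if (abs(slope) < 1e-12) 1 else 0   # exact fit: flat vs sloped
  } else stats::coef(sm)["x", "Pr(>|t|)"]
  list(slope = slope,
       intercept = unname(stats::coef(fit)[1]),
       r_squared = r2,
       p_value = unname(p),
       n = length(x))
}

#' Reversal potential from an I-V sample
#'
#' Zero-crossing of a sampled current-voltage relation by local linear
#' interpolation between the bracketing samples. With multiple crossings
#' the one nearest the median sampled potential is used.
#'
#' @param V Potentials, mV.
#' @param I Currents, pA; must change sign across the sampled range.
#'   Alternatively pass a two-column `(V, I)` object as `V`.
#' @return Reversal potential, mV.
#' @export
reversal_from_iv <- function(V, I) {
  if (missing(I)) {
    m <- as.matrix(V)
    stopifnot(ncol(m) == 2)
    V <- m[, 1]; I <- m[, 2]
  }
  stopifnot(length(V) == length(I), length(V) >= 2)
  o <- order(V)
  V <- V[o]; I <- I[o]
  s <- sign(I)
  cross <- which(s[-length(s)] * s[-1] < 0)
  exact <- which(I == 0)
  v_cross <- c(V[exact],
               V[cross] - I[cross] * (V[cross + 1] - V[cross]) /
                 (I[cross + 1] - I[cross]))
  if (length(v_cross) == 0)
    stop("current does not change sign over the sampled range",
         call. = FALSE)
  v_cross[which.min(abs(v_cross - stats::median(V)))]
}

#' Extrasynaptic GABA-A reversal potential from cell-attached estimates
#'
#' Combines the resting membrane potential and the agonist-mediated
#' driving force into the extrasynaptic reversal potential under the
#' convention DF = Vm - E (a positive DF is depolarizing), i.e.
#' E = Vm - DF. The measurement literature is ambiguous about the sign
#' in which the driving force is reported, so the opposite convention
#' (DF = E - Vm) is available behind `df_convention`.
#'
#' @param Vm_mV Resting membrane potential, mV.
#' @param DF_mV Driving force measured under the extrasynaptic agonist
#'   (THIP), mV.
#' @param df_convention `"vm-minus-e"` (default) or `"e-minus-vm"`.
#' @return Object of class `reversal_estimate`: list with `Vm_mV`,
#'   `DF_mV`, `E_xGABA_mV` and the convention used.
#' @examples
#' estimate_exgaba(-80, -15)$E_xGABA_mV   # -65, the young value
#' @export
estimate_exgaba <- function(Vm_mV, DF_mV,
                            df_convention = c("vm-minus-e", "e-minus-vm")) {
  df_convention <- match.arg(df_convention)
  stopifnot(is.finite(Vm_mV), is.finite(DF_mV))
  E <- switch(df_convention,
              "vm-minus-e" = Vm_mV - DF_mV,
              "e-minus-vm" = Vm_mV + DF_mV)
  structure(list(Vm_mV = Vm_mV, DF_mV = DF_mV, E_xGABA_mV = E,
                 df_convention = df_convention),
            class = "reversal_estimate")
}

#' @export
print.reversal_estimate <- function(x, ...) {
  cat(sprintf("E_xGABA = %.1f mV (Vm = %.1f mV, DF = %.1f mV, %s)\n",
              x$E_xGABA_mV, x$Vm_mV, x$DF_mV, x$df_convention))
  invisible(x)
}
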