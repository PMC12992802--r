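#' Spike data container
#'
#' Event-list representation of the spiking of one cell population.
#'
#' @param cell Integer cell indices (1-based), one per spike.
#' @param time Spike times, s, within `[0, duration]`.
#' @param n_cells Number of cells in the population.
#' @param duration Recording duration, s.
#' @param population Population label (e.g. `"GC"`, `"GoC"`, `"MF"`).
#' @return Object of class `spike_data`, sorted by cell then time.
#' @export
spike_data <- function(cell, time, n_cells, duration, population = "") {
  stopifnot(length(cell) == length(time), n_cells >= 1, duration > 0)
  cell <- as.integer(cell)
  if (length(time) > 0) {
    if (min(time) < 0 || max(time) > duration)
      stop("spike times outside [0, duration]", call. = FALSE)
    if (min(cell) < 1 || max(cell) > n_cells)
      stop("cell indices outside 1..n_cells", call. = FALSE)
    o <- order(cell, time)
    cell <- cell[o]; time <- time[o]
  }
  structure(list(cell = cell, time = as.numeric(time),
                 n_cells = as.integer(n_cells), duration = duration,
                 population = population),
            class = "spike_data")
}

#' @export
print.spike_data <- function(x, ...) {
  cat(sprintf("%s spikes: %d events, %d cells, %g s (mean %.2f Hz/cell)\n",
              if (nzchar(x$population)) x$population else "Population",
              length(x$time), x$n_cells, x$duration,
              length(x$time) / x$n_cells / x$duration))
  invisible(x)
}

#' Subset a spike population
#'
#' @param spikes A [spike_data()].
#' @param cells Integer cell indices to keep; the result is re-indexed to
#'   `1..length(cells)`.
#' @return A [spike_data()] over the selected cells.
#' @export
subset_cells <- function(spikes, cells) {
  stopifnot(inherits(spikes, "spike_data"))
  cells <- as.integer(cells)
  keep <- spikes$cell %in% cells
  remap <- match(spikes$cell[keep], cells)
  spike_data(remap, spikes$time[keep], length(cells), spikes$duration,
             spikes$population)
}

#' Population firing-rate estimate by Gaussian filtering
#'
#' Bins spikes at `bin_ms` resolution, converts to a per-cell rate in Hz,
#' and smooths with a unit-area Gaussian kernel of width `sigma_ms`
#' truncated at \eqn{\pm 4 \sigma} and edge-renormalized (near the trace
#' boundaries the kernel mass inside the window is rescaled to 1, so the
#' total spike count is conserved).
#'
#' @param spikes A [spike_data()], or a numeric vector of spike times
#'   (then `n_cells` and `duration` are required).
#' @param sigma_ms Gaussian kernel SD, ms. `0` returns the raw histogram
#'   rate.
#' @param bin_ms Bin width, ms.
#' @param n_cells,duration Used only when `spikes` is a bare numeric
#'   vector.
#' @return Object of class `rate_estimate`: list with `t` (bin centres,
#'   s), `rate` (Hz per cell), `sigma_ms`, `bin_ms`, `n_cells`,
#'   `population`.
#' @export
estimate_rate <- function(spikes, sigma_ms = 20, bin_ms = 1,
                          n_cells = NULL, duration = NULL) {
  if (inherits(spikes, "spike_data")) {
    times <- spikes$time
    n_cells <- spikes$n_cells
    duration <- spikes$duration
    pop <- spikes$population
  } else {
    times <- as.numeric(spikes)
    stopifnot(!is.null(n_cells), !is.null(duration))
    pop <- ""
  }
  bin_s <- bin_ms / 1000
  n_bins <- max(1L, ceiling(duration / bin_s))
  idx <- pmin(n_bins, floor(times / bin_s) + 1L)
  counts <- tabulate(idx, nbins = n_bins)
  rate <- counts / (n_cells * bin_s)
  if (sigma_ms > 0) {
    half <- ceiling(4 * sigma_ms / bin_ms)
    k <- stats::dnorm(seq(-half, half), sd = sigma_ms / bin_ms)
    k <- k / sum(k)
    num <- .conv_same(rate, k)
    den <- .conv_same(rep(1, n_bins), k)  # edge renormalization
    rate <- num / den
  }
  structure(list(t = (seq_len(n_bins) - 0.5) * bin_s, rate = rate,
                 sigma_ms = sigma_ms, bin_ms = bin_ms,
                 n_cells = n_cells, population = pop),
            class = "rate_estimate")
}

# centred convolution, same length as x
.conv_same <- function(x, k) {
  n <- length(x); m <- length(k)
  full <- stats::convolve(x, rev(k), type = "open")
  half <- (m - 1L) %/% 2L
  full[(half + 1L):(half + n)]
}

#' @export
print.rate_estimate <- function(x, ...) {
  cat(sprintf("Rate estimate%s: %d bins of %g ms, sigma %g ms, mean %.2f Hz\n",
              if (nzchar(x$population)) paste0(" (", x$population, ")")
              else "", length(x$rate), x$bin_ms, x$sigma_ms,
              mean(x$rate)))
  invisible(x)
}

#' Classify granule cells as ON (in-zone) or OFF
#'
#' A granule cell is ON if at least one of its mossy-fibre inputs comes
#' from a glomerulus inside the stimulation zone, OFF otherwise.
#'
#' @param conn A [build_connectivity()] result (carries its geometry).
#' @param protocol An [input_protocol()] (the zone rectangle is used).
#' @return Character vector `"ON"`/`"OFF"` per GC.
#' @export
classify_on_off <- function(conn, protocol) {
  stopifnot(inherits(conn, "gl_connectivity"),
            inherits(protocol, "input_protocol"))
  geom <- conn$geometry
  in_zone <- .in_zone(geom$mf_pos, protocol$zone)
  on <- logical(geom$counts[["GC"]])
  hit <- in_zone[conn$mf_to_gc$pre]
  on[unique(conn$mf_to_gc$post[hit])] <- TRUE
  ifelse(on, "ON", "OFF")
}

.in_zone <- function(pos, zone) {
  pos[, 1] >= zone[1] & pos[, 1] <= zone[2] &
    pos[, 2] >= zone[3] & pos[, 2] <= zone[4]
}

#' Correlation between input and output rate series
#'
#' Pearson correlation between two rate estimates on the same time grid,
#' excluding an onset transient.
#'
#' @param mf_rate,gc_rate [estimate_rate()] results on identical grids.
#' @param onset_exclude_s Initial span to exclude, s.
#' @return Pearson r, or `NA` (with a warning) for a zero-variance
#'   series.
#' @export
input_output_correlation <- function(mf_rate, gc_rate,
                                     onset_exclude_s = 0.2) {
  stopifnot(inherits(mf_rate, "rate_estimate"),
            inherits(gc_rate, "rate_estimate"))
  if (length(mf_rate$t) != length(gc_rate$t) ||
      max(abs(mf_rate$t - gc_rate$t)) > 1e-9)
    stop("rate estimates are not on the same time grid", call. = FALSE)
  keep <- mf_rate$t > onset_exclude_s
  x <- mf_rate$rate[keep]; y <- gc_rate$rate[keep]
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("zero-variance rate series: correlation undefined")
    return(NA_real_)
  }
  stats::cor(x, y)
}

#' Split rate power into input-driven and oscillatory components
#'
#' Welch periodogram of the mean-subtracted rate (Hann window, 50%
#' overlapping segments), integrated over (i) the input band
#' `f_input` \eqn{\pm} `input_halfwidth` and (ii) the network-oscillation
#' band. If the dominant spectral peak above the input band falls outside
#' the oscillation band, the band is widened to include it (recorded in
#' the result).
#'
#' Before the oscillation band is integrated, the component phase-locked
#' to the input is removed by subtracting the stimulus-cycle-averaged
#' waveform (`remove_locked`): a strongly modulated population rate is a
#' clipped sinusoid whose harmonics extend into the oscillation band,
#' whereas the network-generated rhythm is not phase-locked to the
#' stimulus. This is the classic evoked/induced power decomposition.
#'
#' @param rate An [estimate_rate()] result, duration at least
#'   `10 / f_input`.
#' @param f_input Input modulation frequency, Hz.
#' @param input_halfwidth Half-width of the input band, Hz.
#' @param osc_band Length-2 oscillation band, Hz.
#' @param segment_s Welch segment length, s.
#' @param floor_band Band used to estimate the asynchronous shot-noise
#'   floor of the population rate (median PSD), Hz; the floor is
#'   subtracted (truncated at zero) before integrating the oscillation
#'   band, so `P_osc` measures coherent rhythmic power, not the
#'   firing-rate-dependent Poisson floor. Set to `NULL` to integrate the
#'   raw PSD.
#' @param remove_locked Remove the stimulus-locked (evoked) waveform
#'   before measuring the oscillation band.
#' @return List with `P_input`, `P_osc`, `freq`, `psd`, `osc_band`,
#'   `noise_floor`, `band_widened`.
#' @note The Gaussian rate kernel attenuates the spectrum by
#'   `exp(-(2 pi f sigma)^2)`; for oscillation analysis in the tens of
#'   Hz use a rate estimated with a small `sigma_ms` (e.g. 2 ms or 0).
#' @export
power_split <- function(rate, f_input, input_halfwidth = 0.5,
                        osc_band = c(10, 50), segment_s = 4,
                        floor_band = c(70, 150), remove_locked = TRUE) {
  stopifnot(inherits(rate, "rate_estimate"))
  fs <- 1000 / rate$bin_ms
  dur <- length(rate$rate) / fs
  if (dur < 10 / f_input)
    stop("duration must be at least 10 / f_input", call. = FALSE)
  if (f_input + input_halfwidth >= osc_band[1])
    stop("input band overlaps the oscillation band", call. = FALSE)
  x <- rate$rate - mean(rate$rate)
  w <- .welch_psd(x, fs, min(segment_s, dur / 2))
  in_band <- w$freq >= f_input - input_halfwidth &
    w$freq <= f_input + input_halfwidth
  w_osc <- w
  if (remove_locked) {
    per <- max(1L, round(fs / f_input))  # samples per stimulus cycle
    phase_bin <- ((seq_along(x) - 1L) %% per) + 1L
    locked <- stats::ave(x, phase_bin)
    w_osc <- .welch_psd(x - locked, fs, min(segment_s, dur / 2))
  }
  widened <- FALSE
  cand <- w_osc$freq > f_input + input_halfwidth
  if (any(cand)) {
    f_pk <- w_osc$freq[cand][which.max(w_osc$psd[cand])]
    if (f_pk < osc_band[1] || f_pk > osc_band[2]) {
      osc_band <- c(min(osc_band[1], max(f_input + input_halfwidth,
                                         f_pk - 5)),
                    max(osc_band[2], f_pk + 5))
      widened <- TRUE
    }
  }
  osc <- w_osc$freq >= osc_band[1] & w_osc$freq <= osc_band[2]
  nf <- 0
  if (!is.null(floor_band)) {
    fb <- w_osc$freq >= floor_band[1] & w_osc$freq <= floor_band[2]
    if (any(fb)) nf <- stats::median(w_osc$psd[fb])
  }
  list(P_input = sum(w$psd[in_band]) * w$df,
       P_osc = sum(pmax(0, w_osc$psd[osc] - nf)) * w_osc$df,
       freq = w$freq, psd = w$psd, psd_induced = w_osc$psd,
       osc_band = osc_band, noise_floor = nf, band_widened = widened)
}

# Welch power spectral density: Hann window, 50% overlap, one-sided.
.welch_psd <- function(x, fs, segment_s) {
  L <- max(8L, floor(segment_s * fs))
  L <- min(L, length(x))
  step <- max(1L, L %/% 2L)
  starts <- seq(1L, length(x) - L + 1L, by = step)
  win <- 0.5 - 0.5 * cos(2 * pi * (seq_len(L) - 1) / (L - 1))
  U <- sum(win^2)
  acc <- numeric(L %/% 2L + 1L)
  for (s in starts) {
    seg <- x[s:(s + L - 1L)]
    seg <- (seg - mean(seg)) * win
    sp <- abs(stats::fft(seg))^2 / (fs * U)
    half <- sp[seq_len(L %/% 2L + 1L)]
    # one-sided: double all bins except DC (and Nyquist when L even)
    dbl <- rep(2, length(half)); dbl[1] <- 1
    if (L %% 2L == 0L) dbl[length(half)] <- 1
    acc <- acc + half * dbl
  }
  list(freq = (seq_along(acc) - 1) * fs / L,
       psd = acc / length(starts),
       df = fs / L)
}

#' Bootstrap standard error of a statistic
#'
#' Resamples with replacement `n_iter` times and reports the SD of the
#' bootstrap distribution as the s.e.m., with a percentile 95% CI.
#'
#' @param samples Numeric vector (>= 2 values).
#' @param statistic Function of a numeric vector; default [mean()].
#' @param n_iter Bootstrap iterations.
#' @param seed Integer seed.
#' @return List with `sem`, `ci95` (2.5 and 97.5 percentiles),
#'   `estimate` (statistic of the original sample) and `n_iter`.
#' @export
bootstrap_sem <- function(samples, statistic = mean, n_iter = 1000,
                          seed = 1) {
  stopifnot(length(samples) >= 2, is.function(statistic))
  set.seed(seed)
  n <- length(samples)
  boot <- vapply(seq_len(n_iter), function(i)
    statistic(samples[sample.int(n, n, replace = TRUE)]), numeric(1))
  list(sem = stats::sd(boot),
       ci95 = unname(stats::quantile(boot, c(0.025, 0.975))),
       estimate = statistic(samples),
       n_iter = n_iter)
}
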