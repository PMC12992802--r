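#' Sample stochastic GoC->GC release events
#'
#' The GoC->GC inhibitory synapse is probabilistic: each presynaptic
#' Golgi-cell spike triggers vesicular release independently with
#' probability `cfg$evoked_release_prob`, and each synapse additionally
#' releases miniature events as an independent homogeneous Poisson
#' process at `cfg$spont_release_rate_Hz`.
#'
#' @param presyn_spikes List of numeric vectors, one per synapse, of
#'   presynaptic spike times in s (all within `duration`).
#' @param cfg A [condition_config()].
#' @param duration Duration, s.
#' @param seed Integer seed.
#' @return Object of class `release_train`: list with `times` (sorted, s)
#'   and `source_synapse` (1-based synapse index per event).
#' @examples
#' cfg <- condition_config("adult-wt")
#' rel <- sample_goc_gc_release(list(c(0.1, 0.5), 0.3), cfg, 1, seed = 1)
#' @export
sample_goc_gc_release <- function(presyn_spikes, cfg, duration, seed = 1) {
  stopifnot(inherits(cfg, "condition_config"), duration > 0)
  if (!is.list(presyn_spikes)) presyn_spikes <- list(presyn_spikes)
  set.seed(seed)
  times <- numeric(0); src <- integer(0)
  for (i in seq_along(presyn_spikes)) {
    sp <- as.numeric(presyn_spikes[[i]])
    if (length(sp) > 0) {
      if (any(sp < 0 | sp > duration))
        stop("presynaptic spikes outside [0, duration]", call. = FALSE)
      rel <- sp[stats::runif(length(sp)) < cfg$evoked_release_prob]
      times <- c(times, rel)
      src <- c(src, rep.int(i, length(rel)))
    }
    if (cfg$spont_release_rate_Hz > 0) {
      n_min <- stats::rpois(1, cfg$spont_release_rate_Hz * duration)
      mins <- stats::runif(n_min, 0, duration)
      times <- c(times, mins)
      src <- c(src, rep.int(i, n_min))
    }
  }
  o <- order(times)
  structure(list(times = times[o], source_synapse = src[o],
                 n_synapses = length(presyn_spikes), duration = duration),
            class = "release_train")
}

#' @export
print.release_train <- function(x, ...) {
  cat(sprintf("Release train: %d events from %d synapse(s) over %g s (%.2f Hz)\n",
              length(x$times), x$n_synapses, x$duration,
              length(x$times) / x$duration))
  invisible(x)
}

#' Two-source tonic conductance time course
#'
#' The tonic GABA-A conductance of a granule cell is the sum of an
#' activity-independent constant (astrocytic, Best1-like) and an
#' activity-dependent spillover term: every release event adds
#' `spill_gain_nS_per_event` which decays exponentially with
#' `spill_tau_ms`. By Campbell's theorem the stationary spillover mean
#' under Poisson releases at rate \eqn{\lambda} is
#' \eqn{\lambda \cdot gain \cdot \tau}.
#'
#' @param releases A [sample_goc_gc_release()] result, or a numeric
#'   vector of release times in s.
#' @param cfg A [condition_config()].
#' @param dt_ms Time step of the returned series, ms; must be at most
#'   `spill_tau_ms / 10`.
#' @param duration Duration, s.
#' @return List with `t` (s) and `g` (nS), class `tonic_g_trace`.
#' @export
tonic_conductance_trace <- function(releases, cfg, dt_ms = 1, duration) {
  stopifnot(inherits(cfg, "condition_config"))
  if (dt_ms > cfg$spill_tau_ms / 10)
    stop("dt_ms must be <= spill_tau_ms / 10", call. = FALSE)
  times <- if (inherits(releases, "release_train")) releases$times
  else as.numeric(releases)
  if (missing(duration))
    duration <- if (inherits(releases, "release_train")) releases$duration
    else if (length(times)) max(times) else 1
  n <- ceiling(duration * 1000 / dt_ms)
  t <- (seq_len(n) - 1) * dt_ms / 1000
  # exact per-event exponential decay accumulated on the grid: events are
  # binned to the grid point at or after their time, then the spillover
  # state decays recursively (exact for grid-aligned events)
  g_sp <- numeric(n)
  if (length(times) > 0) {
    bins <- pmin(n, floor(times * 1000 / dt_ms) + 1)
    inc <- tabulate(bins, nbins = n) * cfg$spill_gain_nS_per_event
    a <- exp(-dt_ms / cfg$spill_tau_ms)
    g_sp <- stats::filter(inc, a, method = "recursive")
    g_sp <- as.numeric(g_sp)
  }
  structure(list(t = t, g = cfg$g_tonic_const_nS + g_sp,
                 g_const_nS = cfg$g_tonic_const_nS),
            class = "tonic_g_trace")
}

#' Estimate the GoC->GC convergence needed for a target tonic current
#'
#' Simulates a single voltage-clamped granule cell receiving `N`
#' stochastic GoC synapses (background Golgi firing at
#' `cfg$background_goc_rate_Hz`, evoked release probability and
#' miniature rate from `cfg`) and measures the mean GBZ-sensitive
#' current, `mean(g) * (holding - E_xGABA)`. Returns the smallest `N`
#' whose mean current reaches `target_tonic_pA`, found by doubling then
#' bisection.
#'
#' Per-synapse contributions are simulated with a seed derived from the
#' synapse index, so the simulated mean current is non-decreasing in `N`
#' and the search is well defined.
#'
#' @param cfg A [condition_config()]; its `goc_convergence_mean` is
#'   ignored (it is the quantity being estimated).
#' @param target_tonic_pA Target mean tonic current, pA (> 0).
#' @param holding_mV Holding potential, mV.
#' @param seed Integer seed.
#' @param sim_duration Simulated duration per synapse, s.
#' @param N_max Search ceiling.
#' @return Smallest integer `N` reaching the target.
#' @export
estimate_required_convergence <- function(cfg, target_tonic_pA,
                                          holding_mV = -60, seed = 1,
                                          sim_duration = 50, N_max = 4096) {
  stopifnot(inherits(cfg, "condition_config"))
  if (!(target_tonic_pA > 0))
    stop("target_tonic_pA must be > 0", call. = FALSE)
  DF <- holding_mV - cfg$E_xGABA_mV
  if (DF <= 0)
    stop("holding potential must exceed E_xGABA for an outward-blockable ",
         "tonic current", call. = FALSE)

  tau_s <- cfg$spill_tau_ms / 1000
  syn_mean <- local({
    cache <- numeric(0)
    function(i) {
      while (length(cache) < i) {
        j <- length(cache) + 1
        set.seed((seed + 104729L * j) %% .Machine$integer.max)
        n_sp <- stats::rpois(1, cfg$background_goc_rate_Hz * sim_duration)
        sp <- sort(stats::runif(n_sp, 0, sim_duration))
        rel <- sp[stats::runif(n_sp) < cfg$evoked_release_prob]
        n_min <- stats::rpois(1, cfg$spont_release_rate_Hz * sim_duration)
        rel <- c(rel, stats::runif(n_min, 0, sim_duration))
        # time-mean of the shot-noise conductance over [0, T]: each event
        # contributes gain * tau * (1 - exp(-(T - t)/tau)) / T
        g_bar <- sum(cfg$spill_gain_nS_per_event * tau_s *
                       (1 - exp(-(sim_duration - rel) / tau_s))) /
          sim_duration
        cache[j] <<- g_bar
      }
      cache[i]
    }
  })
  mean_current <- function(N) {
    g <- cfg$g_tonic_const_nS +
      if (N > 0) sum(vapply(seq_len(N), syn_mean, numeric(1))) else 0
    g * DF
  }

  N_max <- as.integer(N_max)
  if (mean_current(1) >= target_tonic_pA) return(1L)
  hi <- 1L
  while (mean_current(hi) < target_tonic_pA) {
    if (hi >= N_max)
      stop("target tonic current unreachable at N_max = ", N_max,
           call. = FALSE)
    hi <- min(N_max, hi * 2L)
  }
  lo <- hi %/% 2L  # mean_current(lo) < target <= mean_current(hi)
  while (hi - lo > 1L) {
    mid <- (lo + hi) %/% 2L
    if (mean_current(mid) >= target_tonic_pA) hi <- mid else lo <- mid
  }
  hi
}
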