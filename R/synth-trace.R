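#' Ground truth for a synthetic tonic-current trace
#'
#' Bundles the generative parameters of a holding-current recording:
#' baseline level, the true pharmacological baseline shifts keyed by
#' transition label (e.g. `"base->TTX"`, `"TTX->GBZ"`), spontaneous IPSC
#' times and amplitudes, and the white-noise SD.
#'
#' @param baseline_pA Baseline holding current, pA (inward currents are
#'   negative, so a typical value is around -200 pA).
#' @param component_shifts Named numeric vector of true baseline shifts in
#'   pA, one per drug transition, named `"<from>-><to>"`. Positive values
#'   are outward shifts (loss of inward tonic current).
#' @param ipsc_times Strictly increasing IPSC onset times, s.
#' @param ipsc_amplitudes IPSC peak amplitudes, pA (positive magnitudes;
#'   rendered as inward transients). Recycled to `length(ipsc_times)`.
#' @param noise_sd Gaussian noise SD, pA.
#' @return Object of class `trace_ground_truth`.
#' @seealso [gen_tonic_trace()], [random_trace_truth()]
#' @export
trace_ground_truth <- function(baseline_pA, component_shifts,
                               ipsc_times = numeric(0),
                               ipsc_amplitudes = numeric(0),
                               noise_sd = 0) {
  stopifnot(is.numeric(baseline_pA), length(baseline_pA) == 1,
            is.numeric(component_shifts), !is.null(names(component_shifts)),
            noise_sd >= 0)
  ipsc_times <- as.numeric(ipsc_times)
  if (length(ipsc_times) > 0) {
    if (any(diff(ipsc_times) <= 0))
      stop("ipsc_times must be strictly increasing", call. = FALSE)
    ipsc_amplitudes <- rep_len(as.numeric(ipsc_amplitudes),
                               length(ipsc_times))
  } else {
    ipsc_amplitudes <- numeric(0)
  }
  structure(list(baseline_pA = baseline_pA,
                 component_shifts = component_shifts,
                 ipsc_times = ipsc_times,
                 ipsc_amplitudes = ipsc_amplitudes,
                 noise_sd = noise_sd),
            class = "trace_ground_truth")
}

#' Randomized trace ground truth for a drug protocol
#'
#' Draws component shifts and a homogeneous Poisson train of IPSCs for a
#' protocol, for use in recovery tests. IPSCs are placed only before the
#' GABA-A blocker (`GBZ`) event, after which synaptic events vanish.
#'
#' @param protocol Ordered character vector of drug labels, e.g.
#'   `c("TTX", "GBZ")`.
#' @param duration Trace duration, s.
#' @param shift_mean,shift_sd Mean and SD (pA) of the true per-transition
#'   shifts (draws are truncated at 0.5 pA from below).
#' @param ipsc_rate_Hz IPSC rate before GBZ, Hz.
#' @param ipsc_amp_mean_pA,ipsc_amp_sd_pA IPSC amplitude distribution, pA.
#' @param noise_sd Gaussian noise SD, pA.
#' @param event_times Drug event times, s; default spaces events evenly.
#' @param seed Integer seed.
#' @return A `trace_ground_truth`.
#' @export
random_trace_truth <- function(protocol, duration, shift_mean = 6,
                               shift_sd = 2, ipsc_rate_Hz = 2,
                               ipsc_amp_mean_pA = 30, ipsc_amp_sd_pA = 5,
                               noise_sd = 2, event_times = NULL,
                               seed = 1) {
  stopifnot(length(protocol) >= 1, duration > 0)
  if (is.null(event_times))
    event_times <- duration * seq_along(protocol) / (length(protocol) + 1)
  labels <- paste0(c("base", protocol[-length(protocol)]), "->", protocol)
  rng <- local({ set.seed(seed); NULL })
  set.seed(seed)
  shifts <- pmax(0.5, stats::rnorm(length(labels), shift_mean, shift_sd))
  names(shifts) <- labels
  gbz_i <- match("GBZ", protocol)
  t_stop <- if (is.na(gbz_i)) duration else event_times[gbz_i]
  n_ev <- stats::rpois(1, ipsc_rate_Hz * t_stop)
  times <- sort(stats::runif(n_ev, 0, t_stop))
  times <- times[c(TRUE, diff(times) > 0)]
  amps <- pmax(5, stats::rnorm(length(times), ipsc_amp_mean_pA,
                               ipsc_amp_sd_pA))
  trace_ground_truth(baseline_pA = -200, component_shifts = shifts,
                     ipsc_times = times, ipsc_amplitudes = amps,
                     noise_sd = noise_sd)
}

#' Generate a synthetic tonic GABA-A holding-current trace
#'
#' Renders a voltage-clamp holding-current recording as the sum of a
#' baseline, cumulative drug-induced baseline shifts (each a smooth
#' logistic wash-in beginning after its application event), inward IPSC
#' transients (instantaneous rise, single-exponential decay), and white
#' Gaussian noise. The ground truth is returned unchanged alongside the
#' trace, so detectors and shift estimators can be scored against it.
#'
#' Wash-in is rendered as a logistic ramp whose 10-90% rise spans about
#' 10 s, centred 15 s after the application event; levels are fully
#' settled well before the default 60-s settling margin used by
#' [drug_shift()].
#'
#' @param protocol Ordered character vector of drug labels applied in
#'   sequence, e.g. `c("TTX", "GBZ")`.
#' @param truth A [trace_ground_truth()] whose `component_shifts` names
#'   must match the transitions implied by `protocol`.
#' @param duration Total duration, s; must leave a pre/post window around
#'   every event.
#' @param rate Sampling rate, Hz (>= 100).
#' @param seed Integer seed for the noise.
#' @param event_times Optional event times, s; default evenly spaced.
#' @param ipsc_tau_ms IPSC decay time constant, ms.
#' @return A list with elements `trace` (a [trace_recording()]) and
#'   `truth` (the input ground truth).
#' @examples
#' tr <- gen_tonic_trace(
#'   c("TTX", "GBZ"),
#'   trace_ground_truth(-200, c("base->TTX" = 5, "TTX->GBZ" = 5)),
#'   duration = 300, rate = 100, seed = 1)
#' range(tr$trace$I)   # a noise-free 3-level staircase
#' @export
gen_tonic_trace <- function(protocol, truth, duration, rate = 500,
                            seed = 1, event_times = NULL,
                            ipsc_tau_ms = 10) {
  stopifnot(inherits(truth, "trace_ground_truth"), duration > 0)
  if (rate < 100)
    stop("sampling rate must be >= 100 Hz", call. = FALSE)
  if (is.null(event_times))
    event_times <- duration * seq_along(protocol) / (length(protocol) + 1)
  if (length(event_times) != length(protocol))
    stop("event_times must match protocol length", call. = FALSE)
  labels <- paste0(c("base", protocol[-length(protocol)]), "->", protocol)
  if (!setequal(labels, names(truth$component_shifts)))
    stop("protocol/truth transition label mismatch: expected ",
         paste(labels, collapse = ", "), call. = FALSE)
  if (length(truth$ipsc_times) > 0 &&
      max(truth$ipsc_times) >= duration)
    stop("ipsc_times must lie within the trace duration", call. = FALSE)

  n <- floor(duration * rate)
  t <- seq_len(n) / rate
  I <- rep(truth$baseline_pA, n)

  # drug wash-ins: logistic ramp, 10-90% rise ~10 s, centred 15 s
  # after the event
  ramp_scale <- 10 / (2 * log(9))  # ~2.28 s
  for (k in seq_along(labels)) {
    sh <- truth$component_shifts[[labels[k]]]
    if (sh != 0)
      I <- I + sh / (1 + exp(-(t - event_times[k] - 15) / ramp_scale))
  }

  # IPSC transients: inward (negative), instant rise, exponential decay
  tau_s <- ipsc_tau_ms / 1000
  kern_n <- ceiling(8 * tau_s * rate)
  for (j in seq_along(truth$ipsc_times)) {
    i0 <- floor(truth$ipsc_times[j] * rate) + 1
    idx <- i0:min(n, i0 + kern_n)
    I[idx] <- I[idx] - truth$ipsc_amplitudes[j] *
      exp(-(t[idx] - t[i0]) / tau_s)
  }

  if (truth$noise_sd > 0) {
    set.seed(seed)
    I <- I + stats::rnorm(n, 0, truth$noise_sd)
  }

  events <- data.frame(label = protocol, time = event_times,
                       stringsAsFactors = FALSE)
  list(trace = trace_recording(t, I, events), truth = truth)
}
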