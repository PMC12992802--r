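#' Canonical granular-layer inhibition conditions
#'
#' Returns the parameter set describing Golgi-cell (GoC) to granule-cell
#' (GC) inhibition for one of the four experimental conditions
#' (age \eqn{\times} genotype). The sets encode the measured structure of
#' cerebellar tonic inhibition:
#' \itemize{
#'   \item adult GCs are inhibited by 8 GoCs on average; young wild-type
#'     (WT) and Best1-knockout (KO) animals require 4 and 3 times more
#'     converging GoC inputs, respectively;
#'   \item the per-synapse miniature (action-potential-independent) release
#'     rate falls with maturation to 1/3 (WT) and 1/2 (KO) of its young
#'     value;
#'   \item the extrasynaptic GABA-A reversal potential shifts from -65 mV
#'     (young) to -80 mV (adult);
#'   \item the activity-independent ("Best1-like") tonic conductance is
#'     reduced in the KO, and a homeostatic outward K+ gain >= 1 restores
#'     the WT rheobase.
#' }
#' Values are shipped as versioned JSON in `inst/extdata/conditions.json`.
#'
#' @param age `"young"` or `"adult"`.
#' @param genotype `"WT"` or `"Best1KO"` (aliases `"wt"`, `"ko"`,
#'   `"best1ko"` accepted), or pass a single canonical name such as
#'   `"young-wt"` as `age` and leave `genotype` missing.
#'
#' @return An object of class `condition_config`: a list with fields
#'   `name`, `age`, `genotype`, `goc_convergence_mean`,
#'   `spont_release_rate_Hz`, `evoked_release_prob`, `g_tonic_const_nS`,
#'   `spill_gain_nS_per_event`, `spill_tau_ms`, `background_goc_rate_Hz`,
#'   `E_xGABA_mV` and `k_current_gain`.
#'
#' @examples
#' cfg <- condition_config("adult", "WT")
#' cfg$goc_convergence_mean   # 8
#' condition_config("young-wt")$E_xGABA_mV   # -65
#' @export
condition_config <- function(age, genotype) {
  if (missing(genotype)) {
    name <- match.arg(tolower(age),
                      c("young-wt", "young-ko", "adult-wt", "adult-ko"))
  } else {
    age <- match.arg(tolower(age), c("young", "adult"))
    gt <- switch(tolower(genotype),
                 "wt" = "wt", "best1ko" = "ko", "ko" = "ko", "best1-ko" = "ko",
                 stop("unknown genotype: ", genotype, call. = FALSE))
    name <- paste0(age, "-", gt)
  }
  tbl <- .conditions_table()
  raw <- tbl$conditions[[name]]
  cfg <- c(list(name = name), raw, tbl$defaults)
  cfg$k_current_gain <- .k_gain_closed_form(cfg, tbl)
  structure(cfg, class = "condition_config")
}

.conditions_table <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      path <- system.file("extdata", "conditions.json", package = "tonicgl",
                          mustWork = TRUE)
      cache <<- jsonlite::read_json(path, simplifyVector = TRUE)
    }
    cache
  }
})

#' @export
print.condition_config <- function(x, ...) {
  cat(sprintf("Granular-layer condition '%s' (%s %s)\n",
              x$name, x$age, x$genotype))
  cat(sprintf("  GoC->GC convergence:     %g\n", x$goc_convergence_mean))
  cat(sprintf("  miniature release rate:  %g Hz/synapse\n",
              x$spont_release_rate_Hz))
  cat(sprintf("  evoked release prob.:    %g\n", x$evoked_release_prob))
  cat(sprintf("  tonic conductance:       %g nS const + %g nS/event (tau %g ms)\n",
              x$g_tonic_const_nS, x$spill_gain_nS_per_event, x$spill_tau_ms))
  cat(sprintf("  E_xGABA:                 %g mV\n", x$E_xGABA_mV))
  cat(sprintf("  homeostatic K+ gain:     %.4f\n", x$k_current_gain))
  invisible(x)
}

#' Granule-cell point-neuron parameters
#'
#' Conductance-based leaky integrate-and-fire parameters used throughout
#' the single-cell and network simulations. These replace detailed
#' multicompartmental models while preserving the manipulated variables
#' (inhibitory convergence, release rates, tonic conductance, reversal
#' potential).
#'
#' @return Named list: capacitance `C_pF`, leak `gL_nS` (the membrane
#'   time constant is 10 ms, so the measured tonic conductances are a
#'   substantial share of the input conductance, as in real GCs),
#'   leak/resting potential `EL_mV`, threshold `Vth_mV`, reset
#'   `Vreset_mV`, absolute refractory period `refrac_ms`, excitatory
#'   reversal `Ee_mV`, excitatory and inhibitory synaptic decay
#'   constants `tau_e_ms`, `tau_i_ms`, per-release fast IPSC conductance
#'   `ipsc_g_nS`, and the baseline outward K+ current `I_K_base_pA`
#'   scaled by the homeostatic gain.
#' @export
gc_neuron_params <- function() {
  list(C_pF = 3, gL_nS = 0.3, EL_mV = -80, Vth_mV = -40, Vreset_mV = -80,
       refrac_ms = 2, Ee_mV = 0, tau_e_ms = 2, tau_i_ms = 10,
       ipsc_g_nS = 0.4, I_K_base_pA = 2)
}

# Mean tonic conductance (nS) of a GC under background GoC firing:
# constant term plus the stationary mean of the shot-noise spillover
# process (Campbell's theorem, lambda * gain * tau).
.mean_tonic_g <- function(cfg) {
  lam <- cfg$goc_convergence_mean *
    (cfg$background_goc_rate_Hz * cfg$evoked_release_prob +
       cfg$spont_release_rate_Hz)
  cfg$g_tonic_const_nS + lam * cfg$spill_gain_nS_per_event *
    (cfg$spill_tau_ms / 1000)
}

# Closed-form homeostatic K+ gain. The compensation scales a constant
# outward K+ current (subtractive): a GC's rheobase is
# I_rh = gL (Vth - EL) + g_tonic (Vth - E_xGABA) + k I_K_base, so the
# gain restoring the same-age WT rheobase despite the reduced tonic
# conductance is k = 1 + (g_WT - g_KO)(Vth - E) / I_K_base. Being a
# current and not a conductance, the compensation restores baseline
# excitability without restoring the shunt: the KO keeps a higher f-I
# gain, as observed. WT gain is 1 by definition.
.k_gain_closed_form <- function(cfg, tbl) {
  if (identical(cfg$genotype, "WT")) return(1)
  wt_name <- paste0(cfg$age, "-wt")
  wt <- c(tbl$conditions[[wt_name]], tbl$defaults)
  p <- gc_neuron_params()
  g_wt <- .mean_tonic_g(wt)
  g_ko <- .mean_tonic_g(cfg)
  k <- 1 + ((g_wt - g_ko) * (p$Vth_mV - cfg$E_xGABA_mV)) /
    p$I_K_base_pA
  max(1, k)
}

#' Rheobase of a granule cell by simulation
#'
#' Finds the minimal sustained current step that makes a single
#' conductance-based leaky integrate-and-fire GC fire, given the mean
#' tonic inhibitory conductance of a condition and its homeostatic K+
#' gain. Used to verify the homeostatic contract: wild-type and knockout
#' configurations of the same age share the same rheobase.
#'
#' @param cfg A [condition_config()].
#' @param dt_ms Integration step, ms.
#' @param t_max_ms Step duration tested, ms.
#' @param tol_pA Bisection tolerance, pA.
#' @return Rheobase current in pA.
#' @export
rheobase_gc <- function(cfg, dt_ms = 0.05, t_max_ms = 500, tol_pA = 0.01) {
  p <- gc_neuron_params()
  g_t <- .mean_tonic_g(cfg)
  fires <- function(I_pA) {
    .lif_first_spike(I_pA, g_t, cfg$E_xGABA_mV, cfg$k_current_gain,
                     dt_ms, t_max_ms) >= 0
  }
  lo <- 0; hi <- 1
  while (!fires(hi)) {
    hi <- hi * 2
    if (hi > 1e4) stop("rheobase search failed to bracket", call. = FALSE)
  }
  while (hi - lo > tol_pA) {
    mid <- (lo + hi) / 2
    if (fires(mid)) hi <- mid else lo <- mid
  }
  hi
}

#' First-spike latency of a granule cell under a current step
#'
#' @inheritParams rheobase_gc
#' @param I_pA Injected current step, pA.
#' @return Latency in ms, or `NA` if the cell does not fire within
#'   `t_max_ms`.
#' @export
first_spike_latency <- function(cfg, I_pA, dt_ms = 0.05, t_max_ms = 500) {
  g_t <- .mean_tonic_g(cfg)
  lat <- .lif_first_spike(I_pA, g_t, cfg$E_xGABA_mV, cfg$k_current_gain,
                          dt_ms, t_max_ms)
  if (lat < 0) NA_real_ else lat
}

# Exponential-Euler single LIF with constant tonic conductance and the
# homeostatic outward K+ current; returns first-spike time in ms or -1.
.lif_first_spike <- function(I_pA, g_tonic_nS, E_gaba_mV, k_gain,
                             dt_ms, t_max_ms) {
  p <- gc_neuron_params()
  n <- ceiling(t_max_ms / dt_ms)
  V <- p$EL_mV
  g_sum <- p$gL_nS + g_tonic_nS
  Vinf <- (p$gL_nS * p$EL_mV + g_tonic_nS * E_gaba_mV + I_pA -
             k_gain * p$I_K_base_pA) / g_sum
  a <- exp(-dt_ms * g_sum / p$C_pF)
  for (i in seq_len(n)) {
    V <- Vinf + (V - Vinf) * a
    if (V >= p$Vth_mV) return(i * dt_ms)
  }
  -1
}
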