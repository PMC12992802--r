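#' Build a granular-layer sheet geometry
#'
#' Cell and glomerulus positions for a size-scalable model of a
#' 1.5 mm x 0.7 mm (mediolateral x sagittal) region of the cerebellar
#' granular layer containing, at full scale, about 0.8 million granule
#' cells (GCs), 2000 Golgi cells (GoCs) and 2000 mossy-fibre (MF)
#' glomeruli. At linear scale `s` the sheet dimensions shrink by `s` and
#' the counts by `s^2` (area scaling).
#'
#' At small scales the area-scaled GoC and MF counts would leave the
#' feedback loop and the MF->GC wiring degenerate, so they are
#' floor-capped (GoC and MF at 200) by boosting their density; applied
#' caps are recorded in the returned object. With few Golgi cells each
#' granule cell's inhibition is a sum of a handful of strongly weighted
#' spike trains, whose single-train rate structure contaminates the
#' population spectra; 200 GoCs keep the inhibition pooled.
#'
#' @param scale Linear scale fraction in (0, 1].
#' @param seed Integer seed for the uniform position draws.
#' @param goc_floor,mf_floor Minimum GoC / MF counts at reduced scale.
#' @return Object of class `gl_geometry`: list with `dims_mm`, `scale`,
#'   `counts` (named: GC, GoC, MF), position matrices `gc_pos`,
#'   `goc_pos`, `mf_pos` (columns x = mediolateral, y = sagittal, mm)
#'   and `caps_applied`.
#' @examples
#' g <- build_geometry(0.05, seed = 1)
#' g$counts[["GC"]]   # 2000
#' @export
build_geometry <- function(scale = 1, seed = 1, goc_floor = 200,
                           mf_floor = 200) {
  stopifnot(scale > 0, scale <= 1)
  full <- c(GC = 8e5, GoC = 2000, MF = 2000)
  counts <- round(full * scale^2)
  caps <- character(0)
  if (scale < 1) {
    if (counts[["GoC"]] < goc_floor) {
      counts[["GoC"]] <- min(goc_floor, full[["GoC"]])
      caps <- c(caps, "GoC")
    }
    if (counts[["MF"]] < mf_floor) {
      counts[["MF"]] <- min(mf_floor, full[["MF"]])
      caps <- c(caps, "MF")
    }
  }
  if (any(counts < 10))
    stop("degenerate geometry: a population count fell below 10 at scale ",
         scale, call. = FALSE)
  dims <- c(1.5, 0.7) * scale
  set.seed(seed)
  draw <- function(n) cbind(x = stats::runif(n, 0, dims[1]),
                            y = stats::runif(n, 0, dims[2]))
  structure(list(dims_mm = dims, scale = scale, counts = counts,
                 gc_pos = draw(counts[["GC"]]),
                 goc_pos = draw(counts[["GoC"]]),
                 mf_pos = draw(counts[["MF"]]),
                 caps_applied = caps),
            class = "gl_geometry")
}

#' @export
print.gl_geometry <- function(x, ...) {
  cat(sprintf("Granular-layer sheet %.3f x %.3f mm (scale %g): %d GC, %d GoC, %d MF\n",
              x$dims_mm[1], x$dims_mm[2], x$scale, x$counts[["GC"]],
              x$counts[["GoC"]], x$counts[["MF"]]))
  if (length(x$caps_applied) > 0)
    cat("  density floor applied to:", paste(x$caps_applied,
                                             collapse = ", "), "\n")
  invisible(x)
}

#' Wire the granular-layer network
#'
#' Builds the three edge populations:
#' \itemize{
#'   \item MF->GC: each GC takes its 4 nearest distinct glomeruli within
#'     a dendritic radius;
#'   \item GoC->GC: each GC draws Poisson(`cfg$goc_convergence_mean`)
#'     distinct presynaptic GoCs with proximity-decaying weights;
#'   \item GC->GoC (parallel fibre): each GC's PF runs mediolaterally and
#'     contacts, with probability `pf_conn_prob`, every GoC whose
#'     sagittal position lies within `pf_halfwidth_mm` of the PF; the
#'     edge delay grows with mediolateral distance (0.5 m/s conduction)
#'     on top of a 1-ms synaptic delay.
#' }
#'
#' @param geom A [build_geometry()].
#' @param cfg A [condition_config()] (GoC->GC convergence).
#' @param seed Integer seed.
#' @param dend_radius_mm GC dendritic reach for glomeruli, mm.
#' @param inh_sigma_mm Proximity scale of GoC->GC sampling weights, mm.
#' @param pf_halfwidth_mm Sagittal half-width of PF->GoC contact, mm.
#' @param pf_conn_prob Connection probability for a PF crossing a GoC.
#' @return Object of class `gl_connectivity`: edge tables `mf_to_gc`,
#'   `goc_to_gc`, `gc_to_goc` (columns `pre`, `post`, `delay_ms`), the
#'   geometry and the config name.
#' @export
build_connectivity <- function(geom, cfg, seed = 1,
                               dend_radius_mm = 0.05,
                               inh_sigma_mm = 0.1,
                               pf_halfwidth_mm = 0.05,
                               pf_conn_prob = 0.1) {
  stopifnot(inherits(geom, "gl_geometry"),
            inherits(cfg, "condition_config"))
  set.seed(seed)
  n_gc <- geom$counts[["GC"]]
  n_goc <- geom$counts[["GoC"]]

  # MF -> GC: 4 nearest glomeruli within the dendritic radius
  nn <- .nearest_k(geom$gc_pos, geom$mf_pos, k = 4,
                   radius = dend_radius_mm)
  if (anyNA(nn))
    stop("dendritic radius too small: a GC found fewer than 4 glomeruli",
         call. = FALSE)
  mf_to_gc <- data.frame(pre = as.vector(t(nn)),
                         post = rep(seq_len(n_gc), each = 4),
                         delay_ms = 1)

  # GoC -> GC: Poisson in-degree, proximity-weighted sampling
  indeg <- pmin(stats::rpois(n_gc, cfg$goc_convergence_mean), n_goc)
  pre <- integer(sum(indeg))
  ptr <- 0L
  for (i in seq_len(n_gc)) {
    k <- indeg[i]
    if (k == 0L) next
    d2 <- (geom$goc_pos[, 1] - geom$gc_pos[i, 1])^2 +
      (geom$goc_pos[, 2] - geom$gc_pos[i, 2])^2
    w <- exp(-d2 / (2 * inh_sigma_mm^2))
    pre[(ptr + 1L):(ptr + k)] <- sample.int(n_goc, k, prob = w)
    ptr <- ptr + k
  }
  goc_to_gc <- data.frame(pre = pre,
                          post = rep(seq_len(n_gc), times = indeg),
                          delay_ms = 1)

  # GC -> GoC via parallel fibres: sagittal band, Bernoulli thinning,
  # mediolateral conduction delay at 0.5 m/s (= 2 ms per mm)
  pf <- .pf_edges(geom$gc_pos, geom$goc_pos, pf_halfwidth_mm,
                  pf_conn_prob)
  gc_to_goc <- data.frame(pre = pf$pre, post = pf$post,
                          delay_ms = 1 + 2 * pf$dist_ml)

  structure(list(mf_to_gc = mf_to_gc, goc_to_gc = goc_to_gc,
                 gc_to_goc = gc_to_goc, geometry = geom,
                 condition = cfg$name),
            class = "gl_connectivity")
}

# k nearest rows of `targets` for each row of `from`, within `radius`;
# returns an n x k index matrix (NA where unavailable). Chunked to bound
# the distance-matrix memory.
.nearest_k <- function(from, targets, k, radius) {
  n <- nrow(from)
  out <- matrix(NA_integer_, n, k)
  chunk <- max(1L, floor(2e7 / nrow(targets)))
  for (s in seq(1L, n, by = chunk)) {
    e <- min(n, s + chunk - 1L)
    d2 <- outer(from[s:e, 1], targets[, 1], "-")^2 +
      outer(from[s:e, 2], targets[, 2], "-")^2
    for (r in seq_len(e - s + 1L)) {
      o <- order(d2[r, ])[seq_len(k)]
      ok <- d2[r, o] <= radius^2
      out[s + r - 1L, ok] <- o[ok]
    }
  }
  out
}

.pf_edges <- function(gc_pos, goc_pos, halfwidth, p) {
  pre <- list(); post <- list(); dml <- list()
  for (j in seq_len(nrow(goc_pos))) {
    hits <- which(abs(gc_pos[, 2] - goc_pos[j, 2]) <= halfwidth)
    if (length(hits) == 0) next
    hits <- hits[stats::runif(length(hits)) < p]
    if (length(hits) == 0) next
    pre[[length(pre) + 1L]] <- hits
    post[[length(post) + 1L]] <- rep.int(j, length(hits))
    dml[[length(dml) + 1L]] <- abs(gc_pos[hits, 1] - goc_pos[j, 1])
  }
  list(pre = unlist(pre, use.names = FALSE),
       post = unlist(post, use.names = FALSE),
       dist_ml = unlist(dml, use.names = FALSE))
}

#' @export
print.gl_connectivity <- function(x, ...) {
  n_gc <- x$geometry$counts[["GC"]]
  cat(sprintf("Granular-layer wiring (%s): %d MF->GC, %d GoC->GC (mean in-degree %.2f), %d PF edges\n",
              x$condition, nrow(x$mf_to_gc), nrow(x$goc_to_gc),
              nrow(x$goc_to_gc) / n_gc, nrow(x$gc_to_goc)))
  invisible(x)
}

#' Mossy-fibre input protocol
#'
#' Localized rate-modulated MF drive: glomeruli inside a rectangular zone
#' fire as an inhomogeneous Poisson process with rate
#' `baseline * (1 + depth * sin(2 pi f t))`; out-of-zone glomeruli fire
#' homogeneously at the baseline.
#'
#' @param zone Rectangle `c(x0, x1, y0, y1)` in mm.
#' @param baseline_rate_Hz Baseline MF rate, Hz.
#' @param modulation_depth Fractional modulation depth in `[0, 1]`.
#' @param modulation_freq_Hz Modulation frequency, Hz.
#' @param duration Duration, s.
#' @return Object of class `input_protocol`.
#' @export
input_protocol <- function(zone, baseline_rate_Hz = 20,
                           modulation_depth = 0.8,
                           modulation_freq_Hz = 2, duration = 10) {
  stopifnot(length(zone) == 4, zone[1] < zone[2], zone[3] < zone[4],
            modulation_depth >= 0, modulation_depth <= 1,
            baseline_rate_Hz >= 0, duration > 0)
  structure(list(zone = as.numeric(zone),
                 baseline_rate_Hz = baseline_rate_Hz,
                 modulation_depth = modulation_depth,
                 modulation_freq_Hz = modulation_freq_Hz,
                 duration = duration),
            class = "input_protocol")
}

#' Central mediolateral input zone
#'
#' Convenience constructor for an [input_protocol()] zone: a central
#' rectangle covering a fraction of the mediolateral extent and (by
#' default) the full sagittal extent of the sheet.
#'
#' @param geom A [build_geometry()].
#' @param frac_x,frac_y Fractions of each extent covered.
#' @return Length-4 zone rectangle, mm.
#' @export
central_zone <- function(geom, frac_x = 0.25, frac_y = 1) {
  stopifnot(inherits(geom, "gl_geometry"))
  cx <- geom$dims_mm[1] / 2
  cy <- geom$dims_mm[2] / 2
  c(cx - frac_x * geom$dims_mm[1] / 2, cx + frac_x * geom$dims_mm[1] / 2,
    cy - frac_y * geom$dims_mm[2] / 2, cy + frac_y * geom$dims_mm[2] / 2)
}

#' Generate mossy-fibre input spikes
#'
#' @param geom A [build_geometry()].
#' @param protocol An [input_protocol()]; its zone must lie inside the
#'   sheet.
#' @param seed Integer seed.
#' @return A [spike_data()] for the MF population, with the per-MF
#'   in-zone flag in attribute `"in_zone"`.
#' @export
make_mf_input <- function(geom, protocol, seed = 1) {
  stopifnot(inherits(geom, "gl_geometry"),
            inherits(protocol, "input_protocol"))
  z <- protocol$zone
  if (z[1] < 0 || z[3] < 0 || z[2] > geom$dims_mm[1] ||
      z[4] > geom$dims_mm[2])
    stop("input zone extends outside the sheet", call. = FALSE)
  set.seed(seed)
  n_mf <- geom$counts[["MF"]]
  in_zone <- .in_zone(geom$mf_pos, z)
  r0 <- protocol$baseline_rate_Hz
  depth <- protocol$modulation_depth
  f <- protocol$modulation_freq_Hz
  dur <- protocol$duration
  cells <- list(); times <- list()
  if (r0 > 0) {
    for (i in seq_len(n_mf)) {
      if (in_zone[i] && depth > 0) {
        # thinning from the envelope rate r0 * (1 + depth)
        n_cand <- stats::rpois(1, r0 * (1 + depth) * dur)
        tc <- sort(stats::runif(n_cand, 0, dur))
        acc <- stats::runif(n_cand) <
          (1 + depth * sin(2 * pi * f * tc)) / (1 + depth)
        tt <- tc[acc]
      } else {
        tt <- sort(stats::runif(stats::rpois(1, r0 * dur), 0, dur))
      }
      if (length(tt) > 0) {
        cells[[length(cells) + 1L]] <- rep.int(i, length(tt))
        times[[length(times) + 1L]] <- tt
      }
    }
  }
  sd <- spike_data(unlist(cells, use.names = FALSE),
                   unlist(times, use.names = FALSE),
                   n_cells = n_mf, duration = dur, population = "MF")
  attr(sd, "in_zone") <- in_zone
  sd
}

#' Simulate the granular-layer network
#'
#' Conductance-based leaky integrate-and-fire simulation of GCs and GoCs
#' with exponential-Euler integration. GCs receive excitatory MF
#' synapses, stochastic GoC->GC inhibition (evoked release with
#' probability `cfg$evoked_release_prob`, miniature releases at
#' `cfg$spont_release_rate_Hz` per synapse; each release adds a fast
#' IPSC conductance and a slow spillover increment to the tonic
#' conductance) and the activity-independent tonic conductance, all with
#' reversal `cfg$E_xGABA_mV`; the knockout's homeostatic K+ gain scales
#' the leak. GoCs are intrinsic pacemakers (constant bias calibrated to
#' `goc_rate_Hz`) excited by parallel fibres.
#'
#' @param geom A [build_geometry()].
#' @param conn A [build_connectivity()] for the same geometry.
#' @param cfg A [condition_config()].
#' @param mf_spikes A [spike_data()] from [make_mf_input()].
#' @param duration Biological time to simulate, s.
#' @param dt_ms Integration step, ms (<= 0.1).
#' @param seed Integer seed for release stochasticity and minis.
#' @param w_mf_nS Peak excitatory conductance per MF spike, nS.
#' @param w_pf_nS Peak PF excitatory conductance per GC spike, nS.
#' @param ipsc_g_nS Fast IPSC conductance per release, nS; default from
#'   [gc_neuron_params()].
#' @param goc_rate_Hz Target intrinsic GoC pacemaker rate, Hz.
#' @return List with `gc` and `goc` [spike_data()] and the integration
#'   settings.
#' @export
simulate_gl <- function(geom, conn, cfg, mf_spikes, duration = 10,
                        dt_ms = 0.05, seed = 1, w_mf_nS = 1.2,
                        w_pf_nS = 0.02, ipsc_g_nS = NULL,
                        goc_rate_Hz = 8) {
  stopifnot(inherits(geom, "gl_geometry"),
            inherits(conn, "gl_connectivity"),
            inherits(cfg, "condition_config"),
            inherits(mf_spikes, "spike_data"))
  if (dt_ms > 0.1)
    stop("dt_ms must be <= 0.1 ms", call. = FALSE)
  n_gc <- geom$counts[["GC"]]
  n_goc <- geom$counts[["GoC"]]
  p <- gc_neuron_params()
  gp <- .goc_params(goc_rate_Hz)

  ord <- order(mf_spikes$time)
  res <- simulate_gl_cpp(
    n_gc = n_gc, n_goc = n_goc,
    mf_pre = conn$mf_to_gc$pre - 1L, mf_post = conn$mf_to_gc$post - 1L,
    mf_delay = conn$mf_to_gc$delay_ms,
    inh_pre = conn$goc_to_gc$pre - 1L, inh_post = conn$goc_to_gc$post - 1L,
    inh_delay = conn$goc_to_gc$delay_ms,
    pf_pre = conn$gc_to_goc$pre - 1L, pf_post = conn$gc_to_goc$post - 1L,
    pf_delay = conn$gc_to_goc$delay_ms,
    mf_spike_cell = mf_spikes$cell[ord] - 1L,
    mf_spike_time = mf_spikes$time[ord],
    n_mf = mf_spikes$n_cells,
    duration_s = duration, dt_ms = dt_ms, seed = as.integer(seed),
    gc_par = c(C = p$C_pF, gL = p$gL_nS,
               EL = p$EL_mV, Vth = p$Vth_mV, Vreset = p$Vreset_mV,
               refrac = p$refrac_ms, Ee = p$Ee_mV, tau_e = p$tau_e_ms,
               tau_i = p$tau_i_ms,
               I_K = cfg$k_current_gain * p$I_K_base_pA),
    goc_par = c(C = gp$C_pF, gL = gp$gL_nS, EL = gp$EL_mV,
                Vth = gp$Vth_mV, Vreset = gp$Vreset_mV,
                refrac = gp$refrac_ms, Ee = gp$Ee_mV,
                tau_e = gp$tau_e_ms, bias = gp$bias_pA,
                b_adapt = gp$b_adapt_nS, tau_adapt = gp$tau_adapt_ms,
                E_adapt = gp$E_adapt_mV, noise_pA = gp$noise_pA),
    syn_par = c(w_mf = w_mf_nS, w_pf = w_pf_nS,
                ipsc_g = if (is.null(ipsc_g_nS)) p$ipsc_g_nS
                         else ipsc_g_nS,
                p_rel = cfg$evoked_release_prob,
                mini_rate = cfg$spont_release_rate_Hz,
                spill_gain = cfg$spill_gain_nS_per_event,
                spill_tau = cfg$spill_tau_ms,
                g_tonic = cfg$g_tonic_const_nS,
                E_gaba = cfg$E_xGABA_mV))
  list(gc = spike_data(res$gc_cell + 1L, res$gc_time, n_gc, duration,
                       "GC"),
       goc = spike_data(res$goc_cell + 1L, res$goc_time, n_goc, duration,
                        "GoC"),
       dt_ms = dt_ms, seed = seed, condition = cfg$name)
}

# GoC pacemaker parameters. A spike-triggered adaptation conductance
# (K+-like) linearizes the f-I curve, so the pacemaker rate is robust to
# parallel-fibre drive; the bias current giving the target intrinsic
# rate is calibrated numerically (bisection on a single simulated cell)
# and cached per target rate.
.goc_params <- local({
  cache <- list()
  function(rate_Hz = 8) {
    par <- list(C_pF = 25, gL_nS = 2, EL_mV = -65, Vth_mV = -50,
                Vreset_mV = -60, refrac_ms = 5, Ee_mV = 0, tau_e_ms = 2,
                b_adapt_nS = 0.3, tau_adapt_ms = 500, E_adapt_mV = -90,
                noise_pA = 18)
    key <- as.character(rate_Hz)
    if (is.null(cache[[key]])) {
      f <- function(I) .goc_rate_single(I, par)
      lo <- 0
      hi <- par$gL_nS * (par$Vth_mV - par$EL_mV) * 4
      while (f(hi) < rate_Hz) hi <- hi * 2
      for (i in 1:25) {
        mid <- (lo + hi) / 2
        if (f(mid) < rate_Hz) lo <- mid else hi <- mid
      }
      cache[[key]] <<- (lo + hi) / 2
    }
    par$bias_pA <- cache[[key]]
    par$rate_Hz <- rate_Hz
    par
  }
})

# firing rate (Hz) of a single adapting GoC under constant bias plus
# the same OU current noise used in the network (fluctuation-driven
# firing keeps the trains irregular); seeded for reproducibility
.goc_rate_single <- function(I_pA, par, dur_s = 6, dt_ms = 0.1) {
  n <- round(dur_s * 1000 / dt_ms)
  burn <- n %/% 6
  set.seed(20231L)
  ou_a <- exp(-dt_ms / 5)
  ou <- stats::rnorm(n) * (par$noise_pA * sqrt(1 - ou_a^2))
  V <- par$EL_mV; ga <- 0; Inoise <- 0; ref <- 0L; spikes <- 0L
  dec_a <- exp(-dt_ms / par$tau_adapt_ms)
  ref_steps <- round(par$refrac_ms / dt_ms)
  for (i in seq_len(n)) {
    ga <- ga * dec_a
    Inoise <- Inoise * ou_a + ou[i]
    if (ref > 0L) { ref <- ref - 1L; next }
    gtot <- par$gL_nS + ga
    Vinf <- (par$gL_nS * par$EL_mV + ga * par$E_adapt_mV + I_pA +
               Inoise) / gtot
    V <- Vinf + (V - Vinf) * exp(-dt_ms * gtot / par$C_pF)
    if (V >= par$Vth_mV) {
      if (i > burn) spikes <- spikes + 1L
      V <- par$Vreset_mV
      ga <- ga + par$b_adapt_nS
      ref <- ref_steps
    }
  }
  spikes / (dur_s * (n - burn) / n)
}
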