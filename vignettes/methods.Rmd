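---
title: "Models and methods: from tonic GABA currents to network coding and gait"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: from tonic GABA currents to network coding and gait}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tonicgl)
```

`tonicgl` implements a chain of analyses around one biological fact:
the tonic GABA-A conductance of cerebellar granule cells (GCs) keeps
its magnitude but switches its source during adolescence, from
activity-dependent synaptic spillover to activity-independent
astrocytic (Best1-mediated) release, while the extrasynaptic reversal
potential E~xGABA~ hyperpolarizes from −65 to −80 mV. This vignette
documents the models, the parameters that matter, the synthetic-data
generators used to validate every stage, the numerical choices, and the
known limitations.

## Tonic-current decomposition (ephys)

A holding-current recording is modelled as baseline + drug-induced
baseline shifts + inward IPSC transients + white noise. The tonic
current is the baseline shift after GABA-A blockade; applying TTX first
splits it into a TTX-sensitive (spillover) and TTX-insensitive
(nonsynaptic) component whose sum equals the total *exactly*, because
the total is defined as the sum of consecutive shifts.

* **Baseline estimator.** The baseline of a window is the mode of a
  Gaussian fitted to the all-point histogram (Freedman–Diaconis bins,
  fit restricted to bins above 20% of the peak count). IPSCs populate
  only the inward tail, so the mode is insensitive to them; this is the
  standard estimator for tonic currents. Fall-backs: kernel-density
  mode, then median. Default windows: 30 s, placed immediately before
  an application event and from 60 s after it (the settling margin);
  both defaults are declared, not inferred from data.
* **IPSC detection.** Matched filter: the trace is detrended with a
  0.25-s running median, cross-correlated with the canonical IPSC
  template (instant rise, exponential decay, τ = 10 ms), and
  thresholded at k = 4 robust SDs (MAD). Because an exponential
  template's autocorrelation is exp(−|Δt|/τ), every accepted event
  predicts a decaying ridge in the filter output; candidates are
  processed largest-first and must exceed the ridge of the already
  accepted events, which suppresses the spurious secondary peaks that
  plain thresholding produces on the decay tail. Detections closer than
  5 ms are merged.
* **Reversal potential.** E~xGABA~ = V~m~ − DF, with DF the driving
  force measured under the δ-subunit-selective agonist THIP. The sign
  convention DF ≡ V~m~ − E (depolarizing force positive) is fixed here
  and exposed as `df_convention`; the opposite reading (`"e-minus-vm"`)
  is available because published driving forces are sometimes reported
  as magnitudes. With V~m~ = −80 mV, a DF of −15 mV gives the young
  value (−65 mV) and a DF of 0 the adult −80 mV.

The synthetic trace generator renders drug wash-ins as logistic ramps
whose 10–90% rise spans ~10 s, centred 15 s after the event — gradual,
as real perfusion is, but fully settled well inside the 60-s margin so
the shift estimator stays unbiased (mean error < 0.1 pA at 2 pA noise
in the test suite).

## Condition parameter sets (gcircuit)

The four canonical conditions (`young-wt`, `young-ko`, `adult-wt`,
`adult-ko`) are shipped as versioned JSON and returned by
`condition_config()`. Their structure is fixed by measurement: adult
GCs are inhibited by 8 Golgi cells (GoCs) on average and the young
wild type/knockout need 4× and 3× more; the per-synapse miniature
release rate falls to 1/3 (WT) and 1/2 (KO) with maturation; E~xGABA~
is −65 mV (young) and −80 mV (adult).

Conductances are calibrated from the measured currents at the
recording driving force (60 mV, symmetric chloride):

* total tonic current 22.36 pA in both ages, with TTX-sensitive
  fractions 63.5% (young) and 22.6% (adult);
* the young nonsynaptic 8.16 pA splits into a Best1-like constant
  (6.15 pA — the part lost in the knockout, 75.4%) and miniature-driven
  spillover (2.01 pA — what remains in the young knockout), which
  pins the spillover gain at 0.035 nS per release given the declared
  background GoC rate (5 Hz, slice-like) and decay (τ = 100 ms);
* the adult knockout retains half of the adult wild-type constant — a
  declared default, since the measured adult residual is significant
  but not printed as a number.

Free constants (evoked release probability 0.5, spillover τ = 100 ms,
background GoC rate 5 Hz) are calibration defaults, not measurements.

**Homeostatic compensation.** The knockout's reduced tonic conductance
is offset by scaling a constant outward K⁺ current (baseline 2 pA),
with the gain solved in closed form so that the knockout's rheobase
equals the same-age wild type's. A *current* (subtractive) rather than
a *conductance* (divisive) compensation is deliberate: it restores
baseline excitability without restoring the shunt, so the knockout
keeps a higher firing-rate gain — which is what is observed. The
numerically simulated rheobases (`rheobase_gc()`) agree across
genotypes to < 0.1 pA.

**Convergence estimation.** `estimate_required_convergence()` rebuilds
the tuning procedure: a voltage-clamped GC receives N stochastic
synapses and the smallest N whose mean GBZ-sensitive current reaches a
target is found by doubling and bisection. Per-synapse contributions
are simulated under synapse-indexed seeds, so the simulated mean is
non-decreasing in N and the search is well defined; inverting the
analytic (Campbell's-theorem) adult mean current recovers N = 8.

## Granular-layer network (netsim)

The sheet is 1.5 × 0.7 mm at full scale with ~0.8 M GCs, 2000 GoCs and
2000 mossy-fibre (MF) glomeruli; at linear scale *s* the dimensions
shrink by *s* and counts by *s*². The working scale is 0.05 (≈2,000
GCs). Because area scaling would leave ~5 GoCs and ~5 glomeruli, both
populations are floor-capped at 200 by a density boost (recorded in
the geometry object). The GoC floor is set high enough that each GC's
inhibition pools many spike trains: with only a handful of Golgi
inputs, the single-train inter-spike-interval structure imprints a
spurious spectral line at the GoC firing rate on the population
activity.

Wiring: each GC takes its 4 nearest glomeruli within a 50-µm dendritic
radius; each GC draws Poisson(convergence) presynaptic GoCs with
proximity-decaying weights (σ = 0.1 mm); each GC's parallel fibre runs
mediolaterally and contacts GoCs within a 50-µm sagittal band with
probability 0.1, with a conduction delay of 2 ms/mm on top of a 1-ms
synaptic delay.

Neurons are conductance-based leaky integrate-and-fire point models —
deliberately so: the variables manipulated across conditions
(convergence, release rates, tonic conductance, E~xGABA~, K⁺ gain) are
preserved, everything else is scaffolding. GC parameters: C = 3 pF,
g~L~ = 0.3 nS (τ~m~ = 10 ms), E~L~ = −80 mV, V~th~ = −40 mV, 2-ms
refractoriness, AMPA-like excitation (τ = 2 ms), fast IPSC conductance
0.4 nS per release (τ = 10 ms) at E~xGABA~. The leak is chosen so that
the measured tonic conductances (~0.3–0.5 nS) are a substantial share
of the input conductance, as they are in real GCs — with a stiffer
leak the tonic switch could not regulate network gain at all. GoCs are
noise-driven pacemakers: Ornstein–Uhlenbeck current noise (SD 18 pA,
τ = 5 ms), spike-triggered adaptation (0.3 nS per spike, τ = 500 ms)
that linearizes the f–I curve, 5% bias heterogeneity, and a bias
current calibrated numerically (bisection on a simulated cell, cached)
to an 8-Hz intrinsic rate. Initial voltages are randomized — identical
deterministic cells started together would fire as an artificially
synchronized population.

Integration is exponential-Euler at dt = 0.05 ms in compiled C++ with
ring-buffered spike delivery; a single seeded RNG stream in a fixed
iteration order makes every raster bit-reproducible. Miniature
releases are generated per GC at its in-degree × per-synapse rate;
every release (evoked or miniature) adds both the fast IPSC and the
slow spillover increment.

The default drive (MF 20 Hz baseline, 2-Hz sinusoidal modulation at
depth 0.8 in a central mediolateral zone of 25% width; MF weight
1.2 nS, PF weight 0.02 nS) puts ON GCs at ~7–9 Hz and GoCs at
~9–11 Hz — the sparse-firing regime. The modulation frequency, depth
and zone size are declared defaults; none is printed in the source
experiments.

## Spike statistics (spikestats)

Rates are per-cell histograms (1-ms bins) convolved with a unit-area
Gaussian (σ = 20 ms, truncated at ±4σ, edge-renormalized); the kernel
conserves the total spike count to < 1%. ON GCs are those with at
least one in-zone glomerulus among their MF inputs. Input–output
correlations are Pearson correlations of population-mean rates on the
common 1-ms grid, excluding a 200-ms onset transient; per-cell rates
are available but population means are the default (the pooled
read-out is the better-determined one at these sizes).

`power_split()` separates input-driven from network-generated power in
a Welch periodogram (4-s Hann segments, 50% overlap). Two refinements
matter:

* a strongly modulated population rate is a clipped sinusoid whose
  harmonics extend far above the input frequency, so the component
  *phase-locked* to the stimulus is removed by subtracting the
  stimulus-cycle-averaged waveform before the oscillation band
  (default 10–50 Hz, auto-widened if the dominant peak lies outside)
  is integrated — the classic evoked/induced decomposition;
* the asynchronous shot-noise floor of a population rate scales with
  the firing rate, so the median PSD of a high-frequency floor band
  (70–150 Hz) is subtracted (truncated at zero) from the oscillation
  band. For spectral work use an unsmoothed rate (`sigma_ms = 0`): the
  20-ms kernel attenuates 20-Hz power 500-fold.

Bootstrap errors follow the resampling convention of the source data:
1,000 iterations, s.e.m. = SD of the bootstrap distribution,
percentile 95% CIs.

## Posture kinematics (kinematics)

Conventions (fixed here; the upstream pose system does not publish
formulas): the body vector runs anus→neck; forelimb vectors
chest→forepaw; hindlimb vectors anus→hindpaw; the limb angle is the 3D
arccos of the normalized dot product and angular speed its unsigned
central difference at the native 20 Hz, without pre-smoothing. Rapid
whole-body motion requires anus speed > 2 cm/s and each forepaw no
higher than the per-frame hindpaw maximum plus 2.576 × the
recording-wide SD of the left–right hindpaw height difference. The
2.576 × SD rule is implemented literally; a percentile alternative of
the same intent exists in the measurement literature, and the SD rule
is the one that is operationally unambiguous. Interlimb correlations
pool all masked frames by default (per-segment averaging is available
through the segmentation path).

Movement segmentation computes translational speed, turning speed,
mean paw height and stride-band power over 0.5/1/2-s windows at a
0.25-s stride, standardizes them, and applies binary segmentation with
a BIC-style penalty (variance estimated from first differences,
multiplier 4 — chosen so that recurring wall-avoidance turning bouts
do not fragment steady locomotion, while a genuine behavioral
transition is localized to within a second). Segment-mean features are
clustered with k-means (k = 8, fixed seed, contiguous labels).

Gait metrics are artifact-defined implementations of common
mouse-gait conventions: strides are peaks of the hindpaw forward
velocity *in the body frame* (relative to the anus, projected on the
heading — invariant to turning and wall encounters); stride-time CV and
step-width CV are SD/mean of inter-stride intervals and of the lateral
hindpaw separation at stance; the ataxia index is the mean unsigned
scatter of lateral hindpaw placements about each side's median track
width, normalized by body length (regular gait re-places the paw at a
reproducible offset, so scatter — not the offset itself — indexes
irregularity); interlimb phase variance is the circular variance of
left-forepaw→right-hindpaw phase lags.

## Synthetic gait generator

The generator emulates open-field recordings in a 20 × 20 × 30 cm
arena (origin at a floor corner, z up, cm): a trunk walking at 6 cm/s
whose heading integrates a prescribed per-segment turning profile and
steers smoothly away from walls (with hysteresis, so the controller
does not chatter; the body orientation is the heading state itself);
nine markers laid out on a juvenile-mouse body plan; paws oscillating
at the stride frequency (default 2.5 Hz — exactly 8 frames per cycle
at 20 Hz, so a perfectly regular gait has strictly zero stride-time
CV). The per-cycle limb waveform is a von Mises-type swing bump,
exp(κ(cosφ − 1)) with κ = 3: the angle changes rapidly during a short
swing and is nearly still in stance, which is what makes the
*unsigned* angular speeds of antiphase limbs negatively correlated at
20 Hz. The left–right structure mixes antiphase and in-phase
components linearly (`lr_phase_mix`; diagonal limbs are trot-coupled),
and the measured LF–RF speed correlation increases strictly with the
mix. Rearing episodes raise the forepaws and head smoothly by several
centimetres. Marker noise is isotropic Gaussian (default 0.5 mm);
optional stride-interval jitter and per-stride lateral placement noise
exist so that the gait metrics can be validated against known ground
truth.

What the generator does **not** emulate: true stance mechanics (paws
follow the trunk rather than planting), camera/pose-estimation error
structure beyond isotropic noise, posture changes other than rearing,
and speed variation within a recording. Passing tests therefore show
that the *analysis* recovers the *generated* coordination structure;
they do not certify performance on real pose data.

## Problem sizes and reproducibility

The shipped tests and the acceptance script use: networks at scale
0.05 (≈2,000 GCs, 200 GoCs/MFs) for 10 s of biological time, 4
conditions × 5 seeds; 100 (tests) or 30 (script) synthetic traces at
200 Hz × 450 s; 20 gait recordings of 60 s plus one 240-s turning
construction. Identical seeds give byte-identical outputs end to end.

## Known limitations

* The oscillation read-out is the one place where this point-neuron
  reduction does not robustly reproduce the source phenomenon. The
  10–50-Hz band power of ON-GC activity is dominated by the
  rate-dependent asynchronous floor plus a loop rhythm whose
  rate-normalized strength is nearly condition-independent here: the
  young conditions' larger convergence does not become a larger
  macroscopic rhythm, because the depolarized young reversal leaves
  mostly shunting (whose gating saturates in both ages) and because
  the model has no Golgi–Golgi coupling to carry volley
  synchronization. The ON-GC input tracking and the age-dependent
  weakening of OFF-GC anticorrelation — the coding results — are
  robust across seeds; the young→adult oscillation-power drop
  comparison between genotypes is not, and `scripts/acceptance.R`
  reports the raw drop values so this can be judged directly.
* File I/O is CSV + JSON sidecars only.
* The tonic targets for the adult knockout and all network drive
  parameters are declared defaults (documented above), not measured
  values.
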