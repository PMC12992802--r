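{
  "version": "1.1",
  "comment": "Canonical granular-layer inhibition parameter sets for the four age x genotype conditions. Convergence and rate ratios follow the measured structure (adult convergence 8; young WT/KO require 4x/3x more inputs; per-synapse miniature release rate falls to 1/3 (WT) and 1/2 (KO) with maturation; extrasynaptic GABA-A reversal shifts from -65 mV to -80 mV). Conductances are calibrated from the measured currents at the recording driving force (60 mV): total tonic 22.36 pA in both ages (TTX-sensitive fraction 63.5% young / 22.6% adult); the young TTX-insensitive 8.16 pA splits into a Best1-like constant (6.15 pA; 75.4% lost in the KO) and miniature-release spillover (2.01 pA), which fixes the per-event spillover gain at the stated background Golgi rate. Adult KO retains half of the adult WT constant (declared default; the measured adult KO residual is significant but unprinted). Free constants (evoked release probability, spillover decay, background Golgi rate) are declared calibration defaults.",
  "defaults": {
    "evoked_release_prob": 0.5,
    "spill_gain_nS_per_event": 0.035,
    "spill_tau_ms": 100,
    "background_goc_rate_Hz": 5
  },
  "conditions": {
    "young-wt": {
      "age": "young",
      "genotype": "WT",
      "goc_convergence_mean": 32,
      "spont_release_rate_Hz": 0.3,
      "g_tonic_const_nS": 0.1025,
      "E_xGABA_mV": -65
    },
    "young-ko": {
      "age": "young",
      "genotype": "Best1KO",
      "goc_convergence_mean": 24,
      "spont_release_rate_Hz": 0.3,
      "g_tonic_const_nS": 0.0085,
      "E_xGABA_mV": -65
    },
    "adult-wt": {
      "age": "adult",
      "genotype": "WT",
      "goc_convergence_mean": 8,
      "spont_release_rate_Hz": 0.1,
      "g_tonic_const_nS": 0.285,
      "E_xGABA_mV": -80
    },
    "adult-ko": {
      "age": "adult",
      "genotype": "Best1KO",
      "goc_convergence_mean": 8,
      "spont_release_rate_Hz": 0.15,
      "g_tonic_const_nS": 0.1425,
      "E_xGABA_mV": -80
    }
  }
}
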