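// Exponential-Euler conductance-based LIF core for the granular-layer
// network: granule cells with MF excitation, stochastic GoC inhibition
// (fast IPSC + slow spillover feeding the tonic conductance) and an
// activity-independent tonic conductance; Golgi cells as pacemakers with
// parallel-fibre excitation. Spike delivery uses per-population ring
// buffers of future conductance increments indexed by delay steps.
#include <Rcpp.h>
#include <random>
#include <vector>
#include <algorithm>
#include <cmath>

using namespace Rcpp;

namespace {

struct Csr {
  std::vector<int> ptr, post, dstep;
  void build(const IntegerVector& pre, const IntegerVector& post_,
             const NumericVector& delay_ms, int n_pre, double dt_ms) {
    ptr.assign(n_pre + 1, 0);
    const int m = pre.size();
    for (int e = 0; e < m; ++e) ptr[pre[e] + 1]++;
    for (int i = 0; i < n_pre; ++i) ptr[i + 1] += ptr[i];
    post.resize(m);
    dstep.resize(m);
    std::vector<int> cur(ptr.begin(), ptr.end() - 1);
    for (int e = 0; e < m; ++e) {
      int k = cur[pre[e]]++;
      post[k] = post_[e];
      dstep[k] = std::max(1, (int)std::lround(delay_ms[e] / dt_ms));
    }
  }
  int max_delay() const {
    int md = 1;
    for (int d : dstep) md = std::max(md, d);
    return md;
  }
};

}  // namespace

// [[Rcpp::export]]
List simulate_gl_cpp(int n_gc, int n_goc,
                     IntegerVector mf_pre, IntegerVector mf_post,
                     NumericVector mf_delay,
                     IntegerVector inh_pre, IntegerVector inh_post,
                     NumericVector inh_delay,
                     IntegerVector pf_pre, IntegerVector pf_post,
                     NumericVector pf_delay,
                     IntegerVector mf_spike_cell,
                     NumericVector mf_spike_time,
                     int n_mf, double duration_s, double dt_ms, int seed,
                     NumericVector gc_par, NumericVector goc_par,
                     NumericVector syn_par) {
  // unpack parameters
  const double gc_C = gc_par["C"], gc_gL = gc_par["gL"],
               gc_EL = gc_par["EL"], gc_Vth = gc_par["Vth"],
               gc_Vreset = gc_par["Vreset"], gc_Ee = gc_par["Ee"],
               gc_tau_e = gc_par["tau_e"], gc_tau_i = gc_par["tau_i"],
               gc_IK = gc_par["I_K"];  // homeostatic outward current, pA
  const int gc_refrac = std::max(1, (int)std::lround(
      (double)gc_par["refrac"] / dt_ms));
  const double go_C = goc_par["C"], go_gL = goc_par["gL"],
               go_EL = goc_par["EL"], go_Vth = goc_par["Vth"],
               go_Vreset = goc_par["Vreset"], go_Ee = goc_par["Ee"],
               go_tau_e = goc_par["tau_e"], go_bias = goc_par["bias"],
               go_b_adapt = goc_par["b_adapt"],
               go_tau_adapt = goc_par["tau_adapt"],
               go_E_adapt = goc_par["E_adapt"],
               go_noise = goc_par["noise_pA"];
  const int go_refrac = std::max(1, (int)std::lround(
      (double)goc_par["refrac"] / dt_ms));
  const double w_mf = syn_par["w_mf"], w_pf = syn_par["w_pf"],
               ipsc_g = syn_par["ipsc_g"], p_rel = syn_par["p_rel"],
               mini_rate = syn_par["mini_rate"],
               spill_gain = syn_par["spill_gain"],
               spill_tau = syn_par["spill_tau"],
               g_tonic = syn_par["g_tonic"], E_gaba = syn_par["E_gaba"];

  const long n_steps = (long)std::lround(duration_s * 1000.0 / dt_ms);

  Csr mf, inh, pf;
  mf.build(mf_pre, mf_post, mf_delay, n_mf, dt_ms);
  inh.build(inh_pre, inh_post, inh_delay, n_goc, dt_ms);
  pf.build(pf_pre, pf_post, pf_delay, n_gc, dt_ms);

  const int L = std::max({mf.max_delay(), inh.max_delay(),
                          pf.max_delay()}) + 2;

  // state
  std::vector<double> Vg(n_gc, gc_EL), ge(n_gc, 0.0), gi(n_gc, 0.0),
      gsp(n_gc, 0.0);
  std::vector<int> refg(n_gc, 0);
  std::vector<double> Vo(n_goc, go_EL), geo(n_goc, 0.0),
      gao(n_goc, 0.0), Inoise(n_goc, 0.0);
  std::vector<int> refo(n_goc, 0);
  // per-GoC Ornstein-Uhlenbeck current noise (tau 5 ms), stationary
  // SD go_noise pA: irregular firing decoheres the pacemaker clock
  const double ou_tau = 5.0;
  const double ou_a = std::exp(-dt_ms / ou_tau);
  const double ou_s = go_noise * std::sqrt(1.0 - ou_a * ou_a);

  // ring buffers of future increments
  std::vector<double> ring_e((size_t)L * n_gc, 0.0),
      ring_i((size_t)L * n_gc, 0.0), ring_sp((size_t)L * n_gc, 0.0),
      ring_eo((size_t)L * n_goc, 0.0);

  const double dec_e = std::exp(-dt_ms / gc_tau_e);
  const double dec_i = std::exp(-dt_ms / gc_tau_i);
  const double dec_sp = std::exp(-dt_ms / spill_tau);
  const double dec_eo = std::exp(-dt_ms / go_tau_e);
  const double dec_ao = std::exp(-dt_ms / go_tau_adapt);

  std::mt19937_64 rng((uint64_t)seed * 0x9E3779B97F4A7C15ULL + 1ULL);
  std::uniform_real_distribution<double> unif(0.0, 1.0);
  std::exponential_distribution<double> expo(1.0);
  std::normal_distribution<double> gauss(0.0, 1.0);

  // desynchronized start and mild pacemaker heterogeneity: identical
  // deterministic cells started at one voltage would fire as an
  // artificially synchronized population
  for (int i = 0; i < n_gc; ++i)
    Vg[i] = gc_EL + (gc_Vth - gc_EL) * 0.8 * unif(rng);
  std::vector<double> go_bias_i(n_goc);
  for (int j = 0; j < n_goc; ++j) {
    Vo[j] = go_Vreset + (go_Vth - go_Vreset) * unif(rng);
    go_bias_i[j] = go_bias * (1.0 + 0.05 * gauss(rng));
  }

  // per-GC miniature release rate (events/ms) from its inhibitory
  // in-degree; next event time sampled exponentially
  std::vector<double> mini_ms(n_gc, 0.0), next_mini(n_gc, -1.0);
  {
    std::vector<int> indeg(n_gc, 0);
    for (size_t e = 0; e < inh.post.size(); ++e) indeg[inh.post[e]]++;
    for (int i = 0; i < n_gc; ++i) {
      mini_ms[i] = indeg[i] * mini_rate / 1000.0;
      next_mini[i] = mini_ms[i] > 0 ? expo(rng) / mini_ms[i] : 2e18;
    }
  }

  std::vector<int> gc_cell, goc_cell;
  std::vector<double> gc_time, goc_time;
  gc_cell.reserve(1 << 16);
  gc_time.reserve(1 << 16);

  long mf_ptr = 0;
  const long n_mf_spk = mf_spike_cell.size();

  for (long s = 0; s < n_steps; ++s) {
    const double t_ms = s * dt_ms;
    const int slot = (int)(s % L);

    // schedule MF spikes emitted in this step
    while (mf_ptr < n_mf_spk &&
           mf_spike_time[mf_ptr] * 1000.0 < t_ms + dt_ms) {
      int c = mf_spike_cell[mf_ptr++];
      for (int e = mf.ptr[c]; e < mf.ptr[c + 1]; ++e) {
        int at = (int)((s + mf.dstep[e]) % L);
        ring_e[(size_t)at * n_gc + mf.post[e]] += w_mf;
      }
    }

    // miniature releases (no conduction delay)
    for (int i = 0; i < n_gc; ++i) {
      while (next_mini[i] <= t_ms) {
        gi[i] += ipsc_g;
        gsp[i] += spill_gain;
        next_mini[i] += expo(rng) / mini_ms[i];
      }
    }

    // apply scheduled increments, then decay
    {
      double* re = &ring_e[(size_t)slot * n_gc];
      double* ri = &ring_i[(size_t)slot * n_gc];
      double* rs = &ring_sp[(size_t)slot * n_gc];
      for (int i = 0; i < n_gc; ++i) {
        ge[i] = ge[i] * dec_e + re[i];
        gi[i] = gi[i] * dec_i + ri[i];
        gsp[i] = gsp[i] * dec_sp + rs[i];
        re[i] = ri[i] = rs[i] = 0.0;
      }
      double* ro = &ring_eo[(size_t)slot * n_goc];
      for (int j = 0; j < n_goc; ++j) {
        geo[j] = geo[j] * dec_eo + ro[j];
        ro[j] = 0.0;
      }
    }

    // integrate GCs
    for (int i = 0; i < n_gc; ++i) {
      if (refg[i] > 0) { --refg[i]; continue; }
      const double g_inh = gi[i] + gsp[i] + g_tonic;
      const double gtot = gc_gL + ge[i] + g_inh;
      const double Vinf =
          (gc_gL * gc_EL + ge[i] * gc_Ee + g_inh * E_gaba - gc_IK) /
          gtot;
      Vg[i] = Vinf + (Vg[i] - Vinf) * std::exp(-dt_ms * gtot / gc_C);
      if (std::abs(Vg[i]) > 200.0)
        stop("integration blow-up in GC %d at t = %g ms", i + 1, t_ms);
      if (Vg[i] >= gc_Vth) {
        gc_cell.push_back(i);
        gc_time.push_back(t_ms / 1000.0);
        Vg[i] = gc_Vreset;
        refg[i] = gc_refrac;
        for (int e = pf.ptr[i]; e < pf.ptr[i + 1]; ++e) {
          int at = (int)((s + pf.dstep[e]) % L);
          ring_eo[(size_t)at * n_goc + pf.post[e]] += w_pf;
        }
      }
    }

    // integrate GoCs (spike-triggered adaptation linearizes the f-I
    // curve and keeps the pacemaker rate stable under PF drive)
    for (int j = 0; j < n_goc; ++j) {
      gao[j] *= dec_ao;
      Inoise[j] = Inoise[j] * ou_a + ou_s * gauss(rng);
      if (refo[j] > 0) { --refo[j]; continue; }
      const double gtot = go_gL + geo[j] + gao[j];
      const double Vinf = (go_gL * go_EL + geo[j] * go_Ee +
                           gao[j] * go_E_adapt + go_bias_i[j] +
                           Inoise[j]) / gtot;
      Vo[j] = Vinf + (Vo[j] - Vinf) * std::exp(-dt_ms * gtot / go_C);
      if (std::abs(Vo[j]) > 200.0)
        stop("integration blow-up in GoC %d at t = %g ms", j + 1, t_ms);
      if (Vo[j] >= go_Vth) {
        goc_cell.push_back(j);
        goc_time.push_back(t_ms / 1000.0);
        Vo[j] = go_Vreset;
        refo[j] = go_refrac;
        gao[j] += go_b_adapt;
        // stochastic evoked release onto each target GC
        for (int e = inh.ptr[j]; e < inh.ptr[j + 1]; ++e) {
          if (unif(rng) < p_rel) {
            int at = (int)((s + inh.dstep[e]) % L);
            ring_i[(size_t)at * n_gc + inh.post[e]] += ipsc_g;
            ring_sp[(size_t)at * n_gc + inh.post[e]] += spill_gain;
          }
        }
      }
    }

    if ((s & 0x3FFF) == 0) Rcpp::checkUserInterrupt();
  }

  return List::create(_["gc_cell"] = gc_cell, _["gc_time"] = gc_time,
                      _["goc_cell"] = goc_cell,
                      _["goc_time"] = goc_time);
}
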