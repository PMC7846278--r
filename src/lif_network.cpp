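#include <Rcpp.h>
#include <random>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Current-based leaky integrate-and-fire network, forward Euler.
// Units: mV, pA, nS, pF, ms. dV/dt = (g_l (v_rest - v) + I) / c_m.
// Exponential synaptic currents: a spike of source j deposits w into the
// target's excitatory (w > 0) or inhibitory (w < 0) synaptic state after a
// fixed conduction delay; states decay with tau_e / tau_i.
//
// syn_ptr (length n+1), syn_tgt, syn_w: CSR adjacency by source neuron
// (0-based). record_idx0: neurons whose voltage is sampled every
// record_every_ms. i_drive: optional per-step current added to every neuron
// (length n_steps, or empty). Noise: white per-step current, per-neuron sd.
// [[Rcpp::export]]
List lif_simulate_cpp(NumericVector v_rest, NumericVector v_th,
                      NumericVector v_reset, NumericVector g_l,
                      NumericVector c_m, NumericVector t_ref_ms,
                      NumericVector i_ext_pa, NumericVector sin_amp_pa,
                      double sin_freq_hz, IntegerVector syn_ptr,
                      IntegerVector syn_tgt, NumericVector syn_w,
                      double tau_e_ms, double tau_i_ms, double delay_ms,
                      double dt_ms, double duration_s,
                      IntegerVector record_idx0, double record_every_ms,
                      NumericVector i_drive, NumericVector noise_sd_pa,
                      int seed) {
  const int n = v_rest.size();
  const long n_steps = (long)std::llround(duration_s * 1000.0 / dt_ms);
  const int n_delay = std::max(1, (int)std::lround(delay_ms / dt_ms));
  const double dec_e = std::exp(-dt_ms / tau_e_ms);
  const double dec_i = std::exp(-dt_ms / tau_i_ms);
  const int ref_steps0 = 0; (void)ref_steps0;

  std::vector<double> v(n), s_e(n, 0.0), s_i(n, 0.0);
  std::vector<int> ref(n, 0);
  std::vector<int> ref_steps(n);
  for (int i = 0; i < n; ++i) {
    v[i] = v_rest[i];
    ref_steps[i] = (int)std::lround(t_ref_ms[i] / dt_ms);
  }
  // delay ring buffer of pending synaptic deposits
  std::vector<double> buf_e((size_t)n_delay * n, 0.0);
  std::vector<double> buf_i((size_t)n_delay * n, 0.0);

  const int n_rec = record_idx0.size();
  const long rec_every = std::max(1L, (long)std::llround(record_every_ms / dt_ms));
  const long n_samples = n_rec > 0 ? n_steps / rec_every : 0;
  NumericMatrix v_rec(n_rec, (int)n_samples);

  std::mt19937_64 rng((unsigned long long)seed);
  std::normal_distribution<double> norm(0.0, 1.0);
  const bool has_drive = i_drive.size() > 0;
  bool has_noise = false;
  for (int i = 0; i < n; ++i) if (noise_sd_pa[i] > 0.0) has_noise = true;

  std::vector<double> spike_t;
  std::vector<int> spike_id;
  const double two_pi_f = 2.0 * M_PI * sin_freq_hz / 1000.0; // per ms

  long rec_count = 0;
  for (long step = 0; step < n_steps; ++step) {
    const int slot = (int)(step % n_delay);
    double *de = &buf_e[(size_t)slot * n];
    double *di = &buf_i[(size_t)slot * n];
    const double t_ms = step * dt_ms;
    const double sinv = sin_freq_hz > 0 ? std::sin(two_pi_f * t_ms) : 0.0;
    const double drive = has_drive ? i_drive[step] : 0.0;

    for (int i = 0; i < n; ++i) {
      // deliver delayed spikes, then decay synaptic states
      s_e[i] = s_e[i] * dec_e + de[i];
      s_i[i] = s_i[i] * dec_i + di[i];
      de[i] = 0.0; di[i] = 0.0;
    }

    for (int i = 0; i < n; ++i) {
      if (ref[i] > 0) {
        --ref[i];
        v[i] = v_reset[i];
        continue;
      }
      double I = s_e[i] + s_i[i] + i_ext_pa[i] + sin_amp_pa[i] * sinv + drive;
      if (has_noise) I += noise_sd_pa[i] * norm(rng);
      v[i] += dt_ms * (g_l[i] * (v_rest[i] - v[i]) + I) / c_m[i];
      if (v[i] < v_th[i] && std::fabs(v[i]) > 200.0)
        stop("lif_simulate: |V| > 200 mV at neuron %d, t = %.3f ms (diverged)",
             i + 1, t_ms);
      if (v[i] >= v_th[i]) {
        spike_t.push_back(t_ms);
        spike_id.push_back(i);
        v[i] = v_reset[i];
        ref[i] = ref_steps[i];
        // schedule synaptic deposits after the conduction delay
        const int dslot = (int)((step + n_delay) % n_delay);
        double *pe = &buf_e[(size_t)dslot * n];
        double *pi_ = &buf_i[(size_t)dslot * n];
        for (int k = syn_ptr[i]; k < syn_ptr[i + 1]; ++k) {
          const double w = syn_w[k];
          if (w > 0) pe[syn_tgt[k]] += w; else pi_[syn_tgt[k]] += w;
        }
      }
    }

    if (n_rec > 0 && (step % rec_every) == 0 && rec_count < n_samples) {
      for (int r = 0; r < n_rec; ++r) v_rec(r, (int)rec_count) = v[record_idx0[r]];
      ++rec_count;
    }
  }

  return List::create(
    _["spike_t_ms"] = NumericVector(spike_t.begin(), spike_t.end()),
    _["spike_id0"] = IntegerVector(spike_id.begin(), spike_id.end()),
    _["v_rec"] = v_rec,
    _["n_steps"] = (double)n_steps);
}
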