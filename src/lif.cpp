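#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

// Conductance-based LIF network integrator.
//
// Scheme: exact exponential decay of the synaptic conductances each step,
// exponential-Euler update of the membrane treating the conductances as
// constant over the step. Spikes are detected at the end-of-step crossing,
// the membrane is reset and clamped for the refractory period. Delayed
// inhibitory arrivals are queued in a circular buffer of conductance
// increments; an arrival queued with delay d (steps) is added to g_in at the
// start of step (spike_step + d).
//
// Units: mV, nS, pF, pA, ms. pA/pF = mV/ms and nS*mV = pA, so no unit
// conversions are needed inside the loop.
//
// All randomness (background and stimulus Poisson trains) is drawn from R's
// RNG, so results are reproducible via set.seed() on the calling side.

// [[Rcpp::export]]
List lif_simulate_cpp(List neuron,
                      IntegerVector syn_offset,   // length n+1, 0-based CSR
                      IntegerVector syn_post,     // 0-based targets
                      NumericVector syn_w,        // |J| in nS (inhibitory)
                      IntegerVector syn_delay,    // delay in steps, >= 1
                      NumericVector bg_lambda,    // expected events/step, per neuron
                      NumericVector bg_w,         // nS per background event
                      List dc_blocks,             // list(targets0, amp, start, stop)
                      List poisson_blocks,        // list(targets0, lambda, w, start, stop)
                      double dt, int n_steps,
                      double inh_scale_from,      // ms; negative = never
                      double inh_scale_factor,
                      IntegerVector record_ids) { // 0-based, may be empty
  NumericVector V_rest = neuron["V_rest"], V_thresh = neuron["V_thresh"],
                C_m = neuron["C_m"], g_L = neuron["g_L"],
                tau_ex = neuron["tau_syn_ex"], tau_in = neuron["tau_syn_in"],
                E_ex = neuron["E_ex"], E_in = neuron["E_in"],
                V_reset = neuron["V_reset"], t_ref = neuron["t_ref"];
  const int n = V_rest.size();

  std::vector<double> V(n), g_ex(n, 0.0), g_in(n, 0.0), I(n, 0.0);
  std::vector<double> dec_ex(n), dec_in(n);
  std::vector<int> refrac(n, 0), ref_steps(n);
  for (int i = 0; i < n; ++i) {
    V[i] = V_rest[i];
    dec_ex[i] = std::exp(-dt / tau_ex[i]);
    dec_in[i] = std::exp(-dt / tau_in[i]);
    ref_steps[i] = (int)std::floor(t_ref[i] / dt + 0.5);
  }

  int max_delay = 1;
  for (int k = 0; k < syn_delay.size(); ++k)
    if (syn_delay[k] > max_delay) max_delay = syn_delay[k];
  const int nslots = max_delay + 1;
  std::vector<double> buf((size_t)nslots * n, 0.0);

  const int n_dc = dc_blocks.size(), n_po = poisson_blocks.size();
  std::vector<IntegerVector> dc_t(n_dc), po_t(n_po);
  std::vector<double> dc_amp(n_dc);
  std::vector<int> dc_start(n_dc), dc_stop(n_dc), po_start(n_po), po_stop(n_po);
  std::vector<double> po_lam(n_po), po_w(n_po);
  for (int b = 0; b < n_dc; ++b) {
    List blk = dc_blocks[b];
    dc_t[b] = blk["targets0"]; dc_amp[b] = as<double>(blk["amp"]);
    dc_start[b] = as<int>(blk["start"]); dc_stop[b] = as<int>(blk["stop"]);
  }
  for (int b = 0; b < n_po; ++b) {
    List blk = poisson_blocks[b];
    po_t[b] = blk["targets0"]; po_lam[b] = as<double>(blk["lambda"]);
    po_w[b] = as<double>(blk["w"]);
    po_start[b] = as<int>(blk["start"]); po_stop[b] = as<int>(blk["stop"]);
  }

  std::vector<int> spk_id;
  std::vector<double> spk_t;
  spk_id.reserve(1 << 16); spk_t.reserve(1 << 16);

  const int n_rec = record_ids.size();
  NumericMatrix Vrec(n_rec > 0 ? n_steps : 0, n_rec);

  bool any_bg = false;
  for (int i = 0; i < n; ++i) if (bg_lambda[i] > 0) { any_bg = true; break; }

  for (int s = 0; s < n_steps; ++s) {
    const double t = s * dt;
    const int slot = s % nslots;
    double *arr = &buf[(size_t)slot * n];

    for (int i = 0; i < n; ++i) {
      g_ex[i] *= dec_ex[i];
      g_in[i] = g_in[i] * dec_in[i] + arr[i];
      arr[i] = 0.0;
    }

    if (any_bg)
      for (int i = 0; i < n; ++i)
        if (bg_lambda[i] > 0) {
          double k = R::rpois(bg_lambda[i]);
          if (k > 0) g_ex[i] += k * bg_w[i];
        }

    for (int b = 0; b < n_po; ++b)
      if (s >= po_start[b] && s < po_stop[b]) {
        const IntegerVector &tg = po_t[b];
        for (int j = 0; j < tg.size(); ++j) {
          double k = R::rpois(po_lam[b]);
          if (k > 0) g_ex[tg[j]] += k * po_w[b];
        }
      }

    for (int b = 0; b < n_dc; ++b) {
      if (s == dc_start[b]) {
        const IntegerVector &tg = dc_t[b];
        for (int j = 0; j < tg.size(); ++j) I[tg[j]] += dc_amp[b];
      }
      if (s == dc_stop[b]) {
        const IntegerVector &tg = dc_t[b];
        for (int j = 0; j < tg.size(); ++j) I[tg[j]] -= dc_amp[b];
      }
    }

    const double inh_f =
      (inh_scale_from >= 0 && t >= inh_scale_from) ? inh_scale_factor : 1.0;

    for (int i = 0; i < n; ++i) {
      if (refrac[i] > 0) {
        --refrac[i];
        V[i] = V_reset[i];
      } else {
        const double gtot = g_L[i] + g_ex[i] + g_in[i];
        const double Vinf = (g_L[i] * V_rest[i] + g_ex[i] * E_ex[i] +
                             g_in[i] * E_in[i] + I[i]) / gtot;
        V[i] = Vinf + (V[i] - Vinf) * std::exp(-dt * gtot / C_m[i]);
        if (!std::isfinite(V[i]))
          stop("integration failure: non-finite membrane potential at t = %f ms",
               t);
        if (V[i] >= V_thresh[i]) {
          spk_id.push_back(i + 1);
          spk_t.push_back(t + dt);
          V[i] = V_reset[i];
          refrac[i] = ref_steps[i];
          const int k0 = syn_offset[i], k1 = syn_offset[i + 1];
          for (int k = k0; k < k1; ++k) {
            const int ds = (s + syn_delay[k]) % nslots;
            buf[(size_t)ds * n + syn_post[k]] += syn_w[k] * inh_f;
          }
        }
      }
    }

    for (int j = 0; j < n_rec; ++j) Vrec(s, j) = V[record_ids[j]];
  }

  List out = List::create(
    _["neuron_id"] = IntegerVector(spk_id.begin(), spk_id.end()),
    _["time_ms"] = NumericVector(spk_t.begin(), spk_t.end()));
  if (n_rec > 0) out["potentials"] = Vrec;
  return out;
}
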