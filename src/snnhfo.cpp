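#include <Rcpp.h>
#include <vector>
#include <cmath>

using namespace Rcpp;

// Analog-delta-modulator emulation on a uniform time grid.
// The error signal tracks the input relative to the value at the last
// tracking reset; a crossing of +/- threshold emits an UP/DN spike, after
// which the modulator holds for `refractory_s` and resumes tracking from the
// signal value at the first grid sample at/after refractory expiry.
// A single modulator serves both polarities (shared refractory clock).
// [[Rcpp::export]]
List adm_encode_cpp(NumericVector x, double fs, double threshold,
                    double refractory_s) {
  const R_xlen_t n = x.size();
  const double dt = 1.0 / fs;
  std::vector<double> up, dn;
  if (n == 0) return List::create(_["up"] = up, _["dn"] = dn);
  double ref = x[0];
  bool holding = false;
  double hold_end = 0.0;
  for (R_xlen_t i = 1; i < n; ++i) {
    const double t = i * dt;
    if (holding) {
      if (t >= hold_end - 1e-12) {
        ref = x[i];       // resume tracking from the value at refractory end
        holding = false;
      }
      continue;           // error is frozen at zero while holding
    }
    const double err = x[i] - ref;
    if (err >= threshold) {
      up.push_back(t);
      holding = true;
      hold_end = t + refractory_s;
    } else if (err <= -threshold) {
      dn.push_back(t);
      holding = true;
      hold_end = t + refractory_s;
    }
  }
  return List::create(_["up"] = up, _["dn"] = dn);
}

static inline int spike_step(double t, double dt, int nsteps) {
  int k = (int)std::floor(t / dt + 1e-9);
  if (k < 0) k = 0;
  if (k >= nsteps) k = nsteps - 1;
  return k;
}

// Clock-driven simulation of the two-layer integrate-and-fire network with
// the dis-inhibitory artifact-rejection stage.
//
// Topology (weights in fA, taus in seconds):
//   UP -> SL_j  exc (w_up[j],  tau_up[j])
//   DN -> SL_j  inh (w_dn[j],  tau_dn[j])
//   UP -> DI    exc (w_up_di,  tau_di_syn)   } single shared synaptic state
//   DN -> DI    exc (w_dn_di,  tau_di_syn)   } (equal tau, summed drive)
//   DI -> GI    inh (w_di_gi,  tau_di_gi)
//   Poisson->GI exc (w_poiss,  tau_poiss)
//   GI -> SL_j  inh (w_gi_sl,  tau_gi_sl)    (shared presynaptic state)
//
// Neurons are leaky integrators of current: exponential-Euler decay of
// synaptic states and of I_mem towards the summed signed input; I_mem is
// floored at 0 (current-mode circuits cannot go negative); threshold
// crossing resets I_mem to 0 and opens a refractory window during which the
// membrane is clamped. Spikes of DI and GI reach their targets one step
// later (one-step axonal delay). Within a step the order is: synaptic decay,
// input application, membrane integration, threshold test, reset.
// [[Rcpp::export]]
List simulate_snn_cpp(NumericVector up_times, NumericVector dn_times,
                      NumericVector poiss_times,
                      double duration_s, double dt,
                      NumericVector w_up, NumericVector tau_up,
                      NumericVector w_dn, NumericVector tau_dn,
                      double w_gi_sl, double tau_gi_sl,
                      double w_up_di, double w_dn_di, double tau_di_syn,
                      double w_di_gi, double tau_di_gi,
                      double w_poiss, double tau_poiss,
                      double tau_mem_sl, double thr_sl, double ref_sl,
                      double tau_mem_di, double thr_di, double ref_di,
                      double tau_mem_gi, double thr_gi, double ref_gi,
                      bool record_traces) {
  const int nsl = w_up.size();
  const int nsteps = (int)std::llround(duration_s / dt);

  // per-step spike counts for the three input streams
  std::vector<std::vector<int> > ext(3);
  for (int s = 0; s < 3; ++s) ext[s].assign(nsteps, 0);
  for (R_xlen_t i = 0; i < up_times.size(); ++i)
    ext[0][spike_step(up_times[i], dt, nsteps)]++;
  for (R_xlen_t i = 0; i < dn_times.size(); ++i)
    ext[1][spike_step(dn_times[i], dt, nsteps)]++;
  for (R_xlen_t i = 0; i < poiss_times.size(); ++i)
    ext[2][spike_step(poiss_times[i], dt, nsteps)]++;

  // synaptic states
  std::vector<double> s_up(nsl, 0.0), s_dn(nsl, 0.0);
  double s_gi_sl = 0.0, s_di = 0.0, s_di_gi = 0.0, s_poiss = 0.0;
  // decay factors
  std::vector<double> d_up(nsl), d_dn(nsl);
  for (int j = 0; j < nsl; ++j) {
    d_up[j] = std::exp(-dt / tau_up[j]);
    d_dn[j] = std::exp(-dt / tau_dn[j]);
  }
  const double d_gi_sl = std::exp(-dt / tau_gi_sl);
  const double d_di = std::exp(-dt / tau_di_syn);
  const double d_di_gi = std::exp(-dt / tau_di_gi);
  const double d_poiss = std::exp(-dt / tau_poiss);
  // membrane decay
  const double dm_sl = std::exp(-dt / tau_mem_sl);
  const double dm_di = std::exp(-dt / tau_mem_di);
  const double dm_gi = std::exp(-dt / tau_mem_gi);

  std::vector<double> imem_sl(nsl, 0.0);
  double imem_di = 0.0, imem_gi = 0.0;
  std::vector<double> refrac_sl(nsl, -1.0);
  double refrac_di = -1.0, refrac_gi = -1.0;

  bool di_fired_prev = false, gi_fired_prev = false;

  std::vector<std::vector<double> > sl_spk(nsl);
  std::vector<double> di_spk, gi_spk;
  std::vector<double> imem_max_sl(nsl, 0.0);

  std::vector<double> tr_di_imem, tr_di_iin, tr_gi_imem, tr_gi_iin,
      tr_sl_imem, tr_sl_iin;
  if (record_traces) {
    tr_di_imem.reserve(nsteps); tr_di_iin.reserve(nsteps);
    tr_gi_imem.reserve(nsteps); tr_gi_iin.reserve(nsteps);
    tr_sl_imem.reserve(nsteps); tr_sl_iin.reserve(nsteps);
  }

  for (int k = 0; k < nsteps; ++k) {
    const double t = k * dt;
    // 1. decay synapses
    for (int j = 0; j < nsl; ++j) { s_up[j] *= d_up[j]; s_dn[j] *= d_dn[j]; }
    s_gi_sl *= d_gi_sl; s_di *= d_di; s_di_gi *= d_di_gi; s_poiss *= d_poiss;
    // 2. apply input spikes of this step + delayed internal spikes
    const int n_up = ext[0][k], n_dn = ext[1][k], n_po = ext[2][k];
    if (n_up > 0)
      for (int j = 0; j < nsl; ++j) s_up[j] += n_up * w_up[j];
    if (n_dn > 0)
      for (int j = 0; j < nsl; ++j) s_dn[j] += n_dn * w_dn[j];
    s_di += n_up * w_up_di + n_dn * w_dn_di;
    s_poiss += n_po * w_poiss;
    if (di_fired_prev) { s_di_gi += w_di_gi; di_fired_prev = false; }
    if (gi_fired_prev) { s_gi_sl += w_gi_sl; gi_fired_prev = false; }
    // 3. integrate membranes (clamped during refractory), floor at 0
    const double iin_di = s_di;
    const double iin_gi = s_poiss - s_di_gi;
    if (t >= refrac_di) {
      imem_di = imem_di * dm_di + iin_di * (1.0 - dm_di);
      if (imem_di < 0.0) imem_di = 0.0;
    } else imem_di = 0.0;
    if (t >= refrac_gi) {
      imem_gi = imem_gi * dm_gi + iin_gi * (1.0 - dm_gi);
      if (imem_gi < 0.0) imem_gi = 0.0;
    } else imem_gi = 0.0;
    double iin_sl0 = 0.0;
    for (int j = 0; j < nsl; ++j) {
      const double iin = s_up[j] - s_dn[j] - s_gi_sl;
      if (j == 0) iin_sl0 = iin;
      if (t >= refrac_sl[j]) {
        imem_sl[j] = imem_sl[j] * dm_sl + iin * (1.0 - dm_sl);
        if (imem_sl[j] < 0.0) imem_sl[j] = 0.0;
      } else imem_sl[j] = 0.0;
      if (imem_sl[j] > imem_max_sl[j]) imem_max_sl[j] = imem_sl[j];
    }
    // 4. threshold, reset, refractory
    if (imem_di >= thr_di && t >= refrac_di) {
      di_spk.push_back(t); imem_di = 0.0; refrac_di = t + ref_di;
      di_fired_prev = true;
    }
    if (imem_gi >= thr_gi && t >= refrac_gi) {
      gi_spk.push_back(t); imem_gi = 0.0; refrac_gi = t + ref_gi;
      gi_fired_prev = true;
    }
    for (int j = 0; j < nsl; ++j) {
      if (imem_sl[j] >= thr_sl && t >= refrac_sl[j]) {
        sl_spk[j].push_back(t); imem_sl[j] = 0.0; refrac_sl[j] = t + ref_sl;
      }
    }
    if (record_traces) {
      tr_di_imem.push_back(imem_di); tr_di_iin.push_back(iin_di);
      tr_gi_imem.push_back(imem_gi); tr_gi_iin.push_back(iin_gi);
      tr_sl_imem.push_back(imem_sl[0]); tr_sl_iin.push_back(iin_sl0);
    }
  }

  List sl(nsl);
  for (int j = 0; j < nsl; ++j) sl[j] = NumericVector(sl_spk[j].begin(), sl_spk[j].end());
  List out = List::create(
      _["sl"] = sl,
      _["di"] = NumericVector(di_spk.begin(), di_spk.end()),
      _["gi"] = NumericVector(gi_spk.begin(), gi_spk.end()),
      _["imem_max_sl"] = NumericVector(imem_max_sl.begin(), imem_max_sl.end()));
  if (record_traces) {
    out["traces"] = List::create(
        _["time_s"] = NumericVector::create(),  // filled in R to save copies
        _["di_imem"] = tr_di_imem, _["di_iin"] = tr_di_iin,
        _["gi_imem"] = tr_gi_imem, _["gi_iin"] = tr_gi_iin,
        _["sl1_imem"] = tr_sl_imem, _["sl1_iin"] = tr_sl_iin);
  }
  return out;
}
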