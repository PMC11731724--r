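// Time-stepping core for the CBGT network simulator.
//
// Conductance-based leaky integrate-and-fire neurons with exponentially
// decaying AMPA/GABA gates and an NMDA gate subject to a voltage-dependent
// magnesium block.  Forward Euler at a fixed step dt (ms).  All randomness
// comes from R's RNG so that set.seed() fully determines a simulation.
//
// Per-step update order (documented in the methods vignette):
//   1. advance the cortical ramp recursion
//   2. integrate membrane potentials of non-refractory neurons
//   3. decay synaptic gates (exact exponential factors)
//   4. draw background input events and increment gates
//   5. detect threshold crossings, reset, start refractory, propagate spikes
//   6. update thalamic sliding-window rates; check the decision boundary

#include <Rcpp.h>
#include <vector>
#include <cmath>
using namespace Rcpp;

static inline double mg_block(double v) {
  // standard [Mg2+] = 1 mM block: 1 / (1 + exp(-0.062 V) / 3.57)
  return 1.0 / (1.0 + 0.28011204 * std::exp(-0.062 * v));
}

// [[Rcpp::export]]
List sim_phase_cpp(List state, List cell, List recep,
                   NumericMatrix W_ampa, NumericMatrix W_nmda,
                   NumericMatrix W_gaba, List bg,
                   NumericVector ramp_target, double ramp_coef,
                   NumericVector drive_const, List freq_windows,
                   List opto_windows, NumericVector I_ext, List th_groups,
                   double threshold, int window_steps, bool check_decision,
                   int max_steps, double dt, IntegerVector pop_index,
                   int n_popcols, bool record_spikes) {
  NumericVector V = clone(as<NumericVector>(state["V"]));
  NumericVector s_ampa = clone(as<NumericVector>(state["s_ampa"]));
  NumericVector s_nmda = clone(as<NumericVector>(state["s_nmda"]));
  NumericVector s_gaba = clone(as<NumericVector>(state["s_gaba"]));
  IntegerVector refr = clone(as<IntegerVector>(state["refr"]));
  NumericVector i_ramp = clone(as<NumericVector>(state["i_ramp"]));

  const int n = V.size();
  NumericVector Cc = cell["C"], Taum = cell["Taum"], Vrest = cell["Vrest"],
                Vthresh = cell["Vthresh"], Vreset = cell["Vreset"],
                VE = cell["VE"], VI = cell["VI"];
  IntegerVector refr_steps = cell["refr_steps"];
  NumericVector dec_ampa = recep["dec_ampa"], dec_gaba = recep["dec_gaba"],
                dec_nmda = recep["dec_nmda"];
  NumericVector bg_rate_a = bg["rate_ampa"], bg_n_a = bg["n_ampa"],
                bg_eff_a = bg["eff_ampa"], bg_rate_g = bg["rate_gaba"],
                bg_n_g = bg["n_gaba"], bg_eff_g = bg["eff_gaba"];

  const double dt_s = dt / 1000.0;  // rates are spikes/s, dt is ms

  // stimulation windows: step-indexed rate increments (AMPA background) and
  // opsin conductances, kept as per-neuron accumulators updated at window
  // boundaries.  g_pos / g_neg sum signed opsin conductances separately so
  // overlapping protocols follow the piecewise opsin current exactly.
  std::vector<double> rate_add(n, 0.0), g_pos(n, 0.0), g_neg(n, 0.0);
  const int nfw = freq_windows.size(), now_ = opto_windows.size();

  const int n_ch = th_groups.size();
  std::vector<std::vector<int>> thg(n_ch);
  for (int c = 0; c < n_ch; ++c) thg[c] = as<std::vector<int>>(th_groups[c]);
  // circular buffers of per-step thalamic spike counts
  std::vector<std::vector<int>> ring(n_ch, std::vector<int>(window_steps, 0));
  std::vector<long> ringsum(n_ch, 0);
  NumericVector th_rate(n_ch);

  IntegerMatrix popcounts(max_steps, n_popcols);
  std::vector<int> sp_step, sp_neuron;

  int decision = 0, decision_step = 0, steps_run = 0;
  std::vector<int> spikers;
  spikers.reserve(64);

  for (int step = 0; step < max_steps; ++step) {
    const int step1 = step + 1;  // 1-based, time = step1 * dt
    // window boundaries: active during [on, off) in 1-based step time
    for (int k = 0; k < nfw; ++k) {
      List w = freq_windows[k];
      int on = w["on"], off = w["off"];
      if (step1 == on || step1 == off) {
        IntegerVector idx = w["idx"];
        double amp = w["amp"];
        double sgn = (step1 == on) ? 1.0 : -1.0;
        for (int j = 0; j < idx.size(); ++j) rate_add[idx[j]] += sgn * amp;
      }
    }
    for (int k = 0; k < now_; ++k) {
      List w = opto_windows[k];
      int on = w["on"], off = w["off"];
      if (step1 == on || step1 == off) {
        IntegerVector idx = w["idx"];
        double amp = w["amp"];
        double sgn = (step1 == on) ? 1.0 : -1.0;
        for (int j = 0; j < idx.size(); ++j) {
          if (amp >= 0) g_pos[idx[j]] += sgn * amp;
          else g_neg[idx[j]] += sgn * amp;
        }
      }
    }

    spikers.clear();
    for (int i = 0; i < n; ++i) {
      // 1. ramp recursion: I_ramp(t) = I_ramp(t-dt) + c [I_target - I_ramp(t-dt)]
      i_ramp[i] += ramp_coef * (ramp_target[i] - i_ramp[i]);

      // 2. threshold check at step start (a neuron sitting at V_thresh
      //    spikes this step), then membrane update for the others
      if (refr[i] > 0) {
        refr[i] -= 1;
      } else if (V[i] >= Vthresh[i]) {
        V[i] = Vreset[i];
        refr[i] = refr_steps[i];
        spikers.push_back(i);
      } else {
        double v = V[i];
        double isyn = s_ampa[i] * (v - VE[i]) +
                      s_nmda[i] * mg_block(v) * (v - VE[i]) +
                      s_gaba[i] * (v - VI[i]);
        // opsin current, verbatim piecewise form; coupled with a minus sign
        // so that g_opto > 0 depolarizes (excitatory) and g_opto < 0
        // hyperpolarizes (inhibitory)
        double iopto = 0.0;
        if (g_pos[i] != 0.0) iopto += g_pos[i] * (v - 0.0);
        if (g_neg[i] != 0.0) iopto += -g_neg[i] * (v + 400.0);
        double dv = dt * ((Vrest[i] - v) / Taum[i] +
                          (I_ext[i] - isyn - iopto) / Cc[i]);
        V[i] = v + dv;
      }

      // 3. gate decay
      s_ampa[i] *= dec_ampa[i];
      s_nmda[i] *= dec_nmda[i];
      s_gaba[i] *= dec_gaba[i];

      // 4. background drive: rate draw ~ N(mean, 1) truncated at 0,
      //    events = rate * n_connections * dt
      if (bg_n_a[i] > 0) {
        double r = bg_rate_a[i] + i_ramp[i] + drive_const[i] + rate_add[i] +
                   norm_rand();
        if (r > 0) s_ampa[i] += bg_eff_a[i] * r * bg_n_a[i] * dt_s;
      }
      if (bg_n_g[i] > 0) {
        double r = bg_rate_g[i] + norm_rand();
        if (r > 0) s_gaba[i] += bg_eff_g[i] * r * bg_n_g[i] * dt_s;
      }
    }

    // propagate spikes; NMDA gates share AMPA-pathway topology via W_nmda
    for (size_t k = 0; k < spikers.size(); ++k) {
      int j = spikers[k];
      popcounts(step, pop_index[j]) += 1;
      if (record_spikes) { sp_step.push_back(step1); sp_neuron.push_back(j + 1); }
      NumericMatrix::Column wa = W_ampa(_, j);
      NumericMatrix::Column wn = W_nmda(_, j);
      NumericMatrix::Column wg = W_gaba(_, j);
      for (int i = 0; i < n; ++i) {
        s_ampa[i] += wa[i];
        s_nmda[i] += wn[i];
        s_gaba[i] += wg[i];
      }
    }

    // 6. thalamic sliding-window rates and decision boundary
    const int slot = step % window_steps;
    for (int c = 0; c < n_ch; ++c) {
      int cnt = 0;
      for (size_t k = 0; k < spikers.size(); ++k) {
        for (size_t m = 0; m < thg[c].size(); ++m)
          if (spikers[k] == thg[c][m]) { ++cnt; break; }
      }
      ringsum[c] += cnt - ring[c][slot];
      ring[c][slot] = cnt;
      th_rate[c] = ringsum[c] /
                   (thg[c].size() * window_steps * dt_s);
    }
    steps_run = step1;

    if (check_decision) {
      double best = -1.0;
      int win = 0, nties = 0;
      for (int c = 0; c < n_ch; ++c) {
        if (th_rate[c] > threshold) {
          if (th_rate[c] > best) { best = th_rate[c]; win = c + 1; nties = 1; }
          else if (th_rate[c] == best) {
            // exact tie: reservoir-style uniform pick under the trial RNG
            ++nties;
            if (unif_rand() < 1.0 / nties) win = c + 1;
          }
        }
      }
      if (win > 0) { decision = win; decision_step = step1; break; }
    }

    if ((step & 511) == 0) {
      for (int i = 0; i < n; ++i)
        if (!std::isfinite(V[i]))
          stop("integration diverged: non-finite potential (neuron %d, step %d)",
               i + 1, step1);
    }
  }
  for (int i = 0; i < n; ++i)
    if (!std::isfinite(V[i]))
      stop("integration diverged: non-finite potential (neuron %d, step %d)",
           i + 1, steps_run);

  List out_state = List::create(
      _["V"] = V, _["s_ampa"] = s_ampa, _["s_nmda"] = s_nmda,
      _["s_gaba"] = s_gaba, _["refr"] = refr, _["i_ramp"] = i_ramp);
  List res = List::create(
      _["state"] = out_state, _["steps_run"] = steps_run,
      _["decision"] = decision, _["decision_step"] = decision_step,
      _["th_rate"] = th_rate, _["popcounts"] = popcounts);
  if (record_spikes)
    res["spikes"] = DataFrame::create(_["step"] = wrap(sp_step),
                                      _["neuron"] = wrap(sp_neuron));
  return res;
}
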