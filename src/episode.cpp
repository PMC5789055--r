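#include <Rcpp.h>
using namespace Rcpp;

// Spike-level integration of one stimulation episode.
//
// Dendritic subunits: tau_b dVb/dt = sum_j w_j E_syn delta(t - t_ij) - Vb,
// integrated with exponential decay plus instantaneous increments
// w * E_syn / tau_b per presynaptic spike.  Soma: leaky integrate-and-fire
// with an AHP adaptation conductance (reset to E_L, g_AHP += a_AHP on a
// spike); synaptic drive I_syn = g_syn * sum_n Vb_n - IPSC.  Inhibition is a
// lumped pool: a low-pass filter of population excitatory spiking scaled by
// g_inh (IPSC >= 0 by construction).  A somatic spike sets the
// backpropagating depolarization of all the neuron's subunits to E_bAP,
// decaying with tau_bAP.  Calcium per synapse accumulates on each
// presynaptic spike as a_Ca * sigmoid((Vb + VbAP - 30)/5) (NMDA-like
// voltage dependence).
//
// Presynaptic spikes arrive as (time, input id) pairs sorted by time and are
// delivered in the step containing their timestamp.  The function is
// deterministic: all randomness lives in the spike trains generated in R.
//
// [[Rcpp::export]]
List run_episode_cpp(int n_neurons, int n_subunits,
                     IntegerVector syn_neuron,   // 0-based
                     IntegerVector syn_subunit,  // 0-based, within neuron
                     NumericVector syn_w,
                     IntegerVector syn_input,    // 0-based presynaptic id
                     NumericVector spike_time,   // sorted ascending (ms)
                     IntegerVector spike_input,  // 0-based
                     double t_end, double dt,
                     double tau_b, double E_syn,
                     double C, double g_L, double E_L, double E_K,
                     double tau_AHP, double a_AHP,
                     double g_syn, double theta_soma,
                     double E_bAP, double tau_bAP,
                     double a_Ca, double tau_inh, double g_inh,
                     bool collect_calcium) {
  const int n_syn = syn_w.size();
  int n_inputs = 0;
  for (int j = 0; j < n_syn; ++j)
    if (syn_input[j] + 1 > n_inputs) n_inputs = syn_input[j] + 1;
  for (int s = 0; s < spike_input.size(); ++s)
    if (spike_input[s] + 1 > n_inputs) n_inputs = spike_input[s] + 1;

  // input id -> synapse indices
  std::vector< std::vector<int> > by_input(n_inputs);
  for (int j = 0; j < n_syn; ++j) by_input[syn_input[j]].push_back(j);

  std::vector<double> Vb(n_neurons * n_subunits, 0.0);
  std::vector<double> V(n_neurons, E_L), gahp(n_neurons, 0.0),
                      vbap(n_neurons, 0.0);
  double s_inh = 0.0;
  NumericVector calcium(n_syn);
  IntegerVector spikes(n_neurons);

  const double dec_b   = std::exp(-dt / tau_b);
  const double dec_ahp = std::exp(-dt / tau_AHP);
  const double dec_bap = std::exp(-dt / tau_bAP);
  const double dec_inh = std::exp(-dt / tau_inh);
  const int n_steps = (int)std::round(t_end / dt);
  int sp = 0;  // cursor into the spike list
  const int n_spk = spike_time.size();

  for (int step = 0; step < n_steps; ++step) {
    const double t_next = (step + 1) * dt;
    // passive decay
    for (size_t b = 0; b < Vb.size(); ++b) Vb[b] *= dec_b;
    for (int n = 0; n < n_neurons; ++n) { gahp[n] *= dec_ahp; vbap[n] *= dec_bap; }
    s_inh *= dec_inh;

    // deliver presynaptic spikes falling in [t, t + dt)
    while (sp < n_spk && spike_time[sp] < t_next) {
      const std::vector<int>& tgt = by_input[spike_input[sp]];
      for (size_t q = 0; q < tgt.size(); ++q) {
        const int j = tgt[q];
        const int b = syn_neuron[j] * n_subunits + syn_subunit[j];
        Vb[b] += syn_w[j] * E_syn / tau_b;
        if (collect_calcium) {
          const double Vloc = Vb[b] + vbap[syn_neuron[j]];
          calcium[j] += a_Ca / (1.0 + std::exp(-(Vloc - 30.0) / 5.0));
        }
      }
      ++sp;
    }

    // somatic update
    for (int n = 0; n < n_neurons; ++n) {
      double sumVb = 0.0;
      const int off = n * n_subunits;
      for (int b = 0; b < n_subunits; ++b) sumVb += Vb[off + b];
      const double Isyn = g_syn * sumVb - g_inh * s_inh;
      V[n] += dt / C * (-g_L * (V[n] - E_L) - gahp[n] * (V[n] - E_K) + Isyn);
      if (V[n] >= theta_soma) {
        V[n] = E_L;
        gahp[n] += a_AHP;
        vbap[n] = E_bAP;
        spikes[n] += 1;
        s_inh += 1.0;
      }
      if (!std::isfinite(V[n]))
        stop("simulation aborted: non-finite somatic voltage (neuron %d)", n + 1);
    }
  }

  return List::create(_["spikes"] = spikes, _["calcium"] = calcium,
                      _["V"] = NumericVector(V.begin(), V.end()),
                      _["Vb"] = NumericVector(Vb.begin(), Vb.end()));
}
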