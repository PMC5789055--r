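#' Parameters of the tagging-and-capture network model
#'
#' Single source of truth for every constant of the two-layer
#' integrate-and-fire network with synaptic tagging and capture.  The
#' structural constants fixed by the model definition are: resting potential
#' `E_L` = 0 mV, initial weight `w_init` = 0.2, potentiation threshold
#' `w_potentiated` = 0.8, PRP capture radius 0.2 a.u., calcium sigmoid
#' centred at 30 mV with 5 mV slope, 20 dendritic subunits per neuron, low /
#' high subunit turnover rates 0.1 / 1.0, 4-s encoding episodes repeated on
#' consecutive days.  The remaining kinetic constants are package defaults
#' chosen once so that coincidence-gated calcium tagging and PRP capture
#' produce full consolidation of a tagged synapse within one between-episode
#' interval (see the methods vignette); all are overridable here.
#'
#' @param n_exc excitatory neurons.
#' @param n_subunits dendritic subunits per neuron.
#' @param n_syn_init synapses per neuron at initialisation.
#' @param n_inputs presynaptic input pool size.
#' @param n_inputs_per_memory inputs per memory ensemble.
#' @param r_stim ensemble firing rate during an episode (Hz).
#' @param t_episode episode length (ms).
#' @param dt integration step (ms).
#' @param tau_b dendritic subunit time constant (ms).
#' @param E_syn synaptic depolarisation scale (mV).
#' @param C somatic capacitance (a.u., with g_L sets the membrane time
#'   constant C/g_L).
#' @param g_L leak conductance.
#' @param E_L resting potential (mV).
#' @param E_K AHP reversal potential (mV).
#' @param tau_AHP,a_AHP adaptation time constant (ms) and quantal increment.
#' @param g_syn dendro-somatic coupling.
#' @param theta_soma spike threshold (mV).
#' @param E_bAP,tau_bAP backpropagating-AP peak (mV) and decay (ms).
#' @param a_Ca maximum calcium influx per presynaptic spike.
#' @param ca_low,ca_high episode-calcium thresholds: below `ca_low` no tag,
#'   between them a depotentiation tag, at or above `ca_high` a potentiation
#'   tag.
#' @param theta_PRP episode-calcium threshold that sets a synapse's PRP
#'   level to its maximum (1.0).
#' @param tau_PRP PRP decay time constant (minutes).
#' @param capture_radius PRP capture radius (a.u. of subunit position).
#' @param consolidation_rate weight change per minute per unit of captured
#'   PRP.
#' @param t_consolidation consolidation-phase duration (minutes).
#' @param w_init initial synaptic weight.
#' @param w_potentiated weight threshold defining a potentiated synapse.
#' @param tau_H homeostatic scaling time constant (days).
#' @param theta_removal turnover-probability scale: a removal-eligible
#'   synapse (w <= w_init) on a subunit with turnover rate r is removed with
#'   probability r * theta_removal per day.
#' @param turnover_low,turnover_high the two subunit turnover rates.
#' @param tau_inh inhibitory low-pass time constant (ms).
#' @param g_inh inhibitory coupling (lumped feedback pool).
#' @return list of class `model_params`.
#' @export
model_params <- function(n_exc = 30,
                         n_subunits = 20,
                         n_syn_init = 200,
                         n_inputs = 200,
                         n_inputs_per_memory = 20,
                         r_stim = 50,
                         t_episode = 4000,
                         dt = 0.1,
                         tau_b = 20,
                         E_syn = 60,
                         C = 1,
                         g_L = 0.1,
                         E_L = 0,
                         E_K = -10,
                         tau_AHP = 200,
                         a_AHP = 0.05,
                         g_syn = 0.15,
                         theta_soma = 10,
                         E_bAP = 40,
                         tau_bAP = 15,
                         a_Ca = 1,
                         ca_low = 4,
                         ca_high = 8,
                         theta_PRP = 8,
                         tau_PRP = 60,
                         capture_radius = 0.2,
                         consolidation_rate = 0.012,
                         t_consolidation = 180,
                         w_init = 0.2,
                         w_potentiated = 0.8,
                         tau_H = 5,
                         theta_removal = 0.2,
                         turnover_low = 0.1,
                         turnover_high = 1.0,
                         tau_inh = 20,
                         g_inh = 1 / 6) {
  p <- as.list(environment())
  with(p, stopifnot(
    tau_b > 0, tau_AHP > 0, tau_bAP > 0, tau_PRP > 0, tau_H > 0, tau_inh > 0,
    dt > 0, t_episode > 0, C > 0,
    w_init > 0, w_init < w_potentiated, w_potentiated <= 1,
    capture_radius > 0, capture_radius <= 1,
    turnover_low < turnover_high,
    ca_low < ca_high,
    n_subunits >= 1, n_exc >= 1, n_syn_init >= 1,
    n_inputs_per_memory <= n_inputs))
  class(p) <- "model_params"
  p
}

#' Calcium influx per presynaptic spike
#'
#' NMDA-receptor-like voltage dependence: a_Ca * 1 / (1 + exp(-(V - 30)/5)),
#' V in mV (local depolarisation, subunit plus backpropagating AP).
#'
#' @param V local depolarisation (mV); vectorised.
#' @param params a [model_params()].
#' @return calcium increment(s).
#' @export
calcium_influx <- function(V, params = model_params()) {
  params$a_Ca / (1 + exp(-(V - 30) / 5))
}

#' Backpropagating action-potential depolarisation
#'
#' V_bAP(t) = E_bAP * exp(-t / tau_bAP) for t >= 0 since the somatic spike;
#' 0 when no spike has occurred (t = Inf).
#'
#' @param t time since the last somatic spike (ms); vectorised.
#' @param params a [model_params()].
#' @return depolarisation (mV).
#' @export
bap_value <- function(t, params = model_params()) {
  if (any(t[is.finite(t)] < 0)) stop("t must be >= 0")
  ifelse(is.finite(t), params$E_bAP * exp(-t / params$tau_bAP), 0)
}
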