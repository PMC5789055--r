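#' Build a network with randomly allocated synapses
#'
#' Each excitatory neuron receives `n_syn_init` synapses from uniformly
#' chosen presynaptic inputs, placed on uniformly chosen dendritic subunits
#' at a uniform position in \[0, 1\] a.u., with weight `w_init`.  The first
#' `n_high_turnover` subunits of every neuron use the high turnover rate,
#' the rest the low rate.
#'
#' @param params a [model_params()].
#' @param n_high_turnover number of high-turnover subunits per neuron
#'   (0 .. `n_subunits`).
#' @return list of class `stc_network`: synapse table (`syn`), per-subunit
#'   turnover rates, simulated-day counter.
#' @export
new_network <- function(params = model_params(), n_high_turnover = 0) {
  stopifnot(n_high_turnover >= 0, n_high_turnover <= params$n_subunits)
  n_tot <- params$n_exc * params$n_syn_init
  syn <- data.frame(
    neuron  = rep(seq_len(params$n_exc), each = params$n_syn_init),
    subunit = sample.int(params$n_subunits, n_tot, replace = TRUE),
    pos     = runif(n_tot),
    w       = rep(params$w_init, n_tot),
    input   = sample.int(params$n_inputs, n_tot, replace = TRUE),
    tag     = 0L,                 # 0 none, +1 potentiation, -1 depotentiation
    prp     = 0,
    birth   = 0L
  )
  subunit_rate <- rep(params$turnover_low, params$n_subunits)
  if (n_high_turnover > 0) {
    subunit_rate[seq_len(n_high_turnover)] <- params$turnover_high
  }
  structure(list(params = params, syn = syn, subunit_rate = subunit_rate,
                 n_high_turnover = n_high_turnover, day = 0L),
            class = "stc_network")
}

#' @export
print.stc_network <- function(x, ...) {
  cat(sprintf("<stc_network> %d neurons x %d subunits | %d synapses | day %d | %d high-turnover subunits\n",
              x$params$n_exc, x$params$n_subunits, nrow(x$syn), x$day,
              x$n_high_turnover))
  invisible(x)
}

#' Sample disjoint memory input ensembles
#'
#' @param params a [model_params()].
#' @param n_memories number of memories.
#' @return list of integer vectors (input ids), pairwise disjoint.
#' @export
make_memories <- function(params = model_params(), n_memories = 1) {
  need <- n_memories * params$n_inputs_per_memory
  if (need > params$n_inputs) stop("input pool too small for disjoint ensembles")
  ids <- sample.int(params$n_inputs, need)
  split(ids, rep(seq_len(n_memories), each = params$n_inputs_per_memory))
}

# homogeneous Poisson trains for the ensemble inputs over one episode
ensemble_spike_trains <- function(ensemble, params) {
  times <- list(); inputs <- list()
  for (id in ensemble) {
    n <- rpois(1, params$r_stim * params$t_episode / 1000)
    if (n > 0) {
      times[[length(times) + 1L]] <- sort(runif(n, 0, params$t_episode))
      inputs[[length(inputs) + 1L]] <- rep(id, n)
    }
  }
  tt <- unlist(times); ii <- unlist(inputs)
  if (is.null(tt)) tt <- numeric(0)
  if (is.null(ii)) ii <- integer(0)
  o <- order(tt)
  list(time = tt[o], input = ii[o])
}

#' Run one 4-s stimulation episode
#'
#' Generates Poisson spike trains for the ensemble inputs and integrates the
#' network at fixed step `dt`.  With `plasticity = TRUE` the per-synapse
#' episode calcium is accumulated for tagging; with `plasticity = FALSE`
#' (recall) only firing is recorded.
#'
#' @param net an `stc_network`.
#' @param ensemble integer input ids to activate.
#' @param plasticity collect calcium for tagging?
#' @param dt override the integration step (ms); defaults to `params$dt`.
#' @param trains optional precomputed spike trains (list with `time`,
#'   `input`), bypassing Poisson generation.
#' @return list: `spikes` (counts per neuron), `rates` (Hz), `calcium`
#'   (per synapse, when collected).
#' @export
run_episode <- function(net, ensemble, plasticity = TRUE, dt = NULL,
                        trains = NULL) {
  p <- net$params
  if (is.null(dt)) dt <- p$dt
  if (is.null(trains)) trains <- ensemble_spike_trains(ensemble, p)
  res <- run_episode_cpp(
    p$n_exc, p$n_subunits,
    net$syn$neuron - 1L, net$syn$subunit - 1L, net$syn$w, net$syn$input - 1L,
    trains$time, trains$input - 1L,
    p$t_episode, dt,
    p$tau_b, p$E_syn, p$C, p$g_L, p$E_L, p$E_K,
    p$tau_AHP, p$a_AHP, p$g_syn, p$theta_soma,
    p$E_bAP, p$tau_bAP, p$a_Ca, p$tau_inh, p$g_inh,
    plasticity)
  list(spikes = res$spikes, rates = res$spikes / (p$t_episode / 1000),
       calcium = res$calcium, V = res$V, Vb = res$Vb)
}

#' Set synaptic tags from episode calcium
#'
#' Episode calcium below `ca_low` leaves no tag; between `ca_low` and
#' `ca_high` a depotentiation tag; at or above `ca_high` a potentiation tag.
#' Calcium at or above `theta_PRP` sets the synapse's PRP level to 1.
#'
#' @param net an `stc_network`.
#' @param calcium per-synapse episode calcium.
#' @return the network with `tag` and `prp` updated (calcium accumulator is
#'   implicitly reset: it is per-episode).
#' @export
update_tags <- function(net, calcium) {
  p <- net$params
  tag <- integer(length(calcium))
  tag[calcium >= p$ca_low & calcium < p$ca_high] <- -1L
  tag[calcium >= p$ca_high] <- 1L
  net$syn$tag <- tag
  net$syn$prp <- ifelse(calcium >= p$theta_PRP, 1, net$syn$prp)
  net
}

#' Consolidation of tagged synapses by PRP capture
#'
#' Tagged synapses capture PRPs from all synapses within `capture_radius`
#' a.u. on the same subunit (including themselves); the captured sum sets
#' the consolidation rate of the tag into the weight.  All PRP levels decay
#' with the single constant `tau_PRP`, so the weight change over the
#' consolidation phase has the closed form
#' dw = rate * dir * P(0) * tau_PRP * (1 - exp(-T / tau_PRP)),
#' applied exactly and then clipped to \[0, 1\]; tags are cleared afterwards
#' and PRP is decayed through the phase.
#'
#' @param net an `stc_network`.
#' @return the network with consolidated weights.
#' @export
consolidate <- function(net) {
  p <- net$params
  syn <- net$syn
  tagged <- which(syn$tag != 0L)
  if (length(tagged) > 0L) {
    integral <- p$tau_PRP * (1 - exp(-p$t_consolidation / p$tau_PRP))
    for (j in tagged) {
      nb <- syn$neuron == syn$neuron[j] & syn$subunit == syn$subunit[j] &
        abs(syn$pos - syn$pos[j]) <= p$capture_radius
      P0 <- sum(syn$prp[nb])
      syn$w[j] <- syn$w[j] +
        p$consolidation_rate * syn$tag[j] * P0 * integral
    }
    syn$w <- pmin(pmax(syn$w, 0), 1)
  }
  syn$tag <- 0L
  syn$prp <- syn$prp * exp(-p$t_consolidation / p$tau_PRP)
  net$syn <- syn
  net
}

#' Homeostatic synaptic scaling
#'
#' dw_j/dt = (1/tau_H) (1 - sum_j w_j / (w_init N_syn)): an identical
#' additive drift on every synapse of a neuron with fixed point
#' sum w = w_init * N_syn.  The total obeys a linear ODE and is advanced by
#' its closed form over `t_days`; the per-synapse change is the total change
#' divided by N_syn, clipped at 0.
#'
#' @param net an `stc_network`.
#' @param t_days elapsed time (days).
#' @return the network with scaled weights.
#' @export
homeostasis <- function(net, t_days = 1) {
  p <- net$params
  syn <- net$syn
  for (n in unique(syn$neuron)) {
    i <- syn$neuron == n
    N <- sum(i)
    S0 <- sum(syn$w[i])
    target <- p$w_init * N
    # dS/dt = (N/tau_H)(1 - S/target): relaxation with time constant
    # tau_H * w_init towards the target sum
    S1 <- target + (S0 - target) * exp(-t_days / (p$tau_H * p$w_init))
    syn$w[i] <- pmax(syn$w[i] + (S1 - S0) / N, 0)
  }
  net$syn <- syn
  net
}

#' Daily stochastic synaptic turnover
#'
#' Synapses not potentiated beyond their initial weight (w <= w_init) are
#' removed with probability (subunit turnover rate) * theta_removal; an
#' equal number of new synapses is added on uniformly chosen subunits of the
#' same neuron, at uniform positions, from uniformly chosen presynaptic
#' inputs, with weight w_init and the current day as birth day.  The synapse
#' count of every neuron is conserved exactly.
#'
#' @param net an `stc_network`.
#' @param day birth-day stamp for added synapses (defaults to the network's
#'   day counter).
#' @return the rewired network.
#' @export
turnover_step <- function(net, day = net$day) {
  p <- net$params
  syn <- net$syn
  eligible <- syn$w <= p$w_init
  p_remove <- net$subunit_rate[syn$subunit] * p$theta_removal
  remove <- eligible & runif(nrow(syn)) < p_remove
  if (any(remove)) {
    per_neuron <- tabulate(syn$neuron[remove], nbins = p$n_exc)
    syn <- syn[!remove, , drop = FALSE]
    n_add <- sum(per_neuron)
    add <- data.frame(
      neuron  = rep(seq_len(p$n_exc), per_neuron),
      subunit = sample.int(p$n_subunits, n_add, replace = TRUE),
      pos     = runif(n_add),
      w       = rep(p$w_init, n_add),
      input   = sample.int(p$n_inputs, n_add, replace = TRUE),
      tag     = 0L, prp = 0, birth = as.integer(day)
    )
    syn <- rbind(syn, add)
    rownames(syn) <- NULL
  }
  net$syn <- syn
  net
}

# one simulated day: episode -> tagging -> consolidation -> homeostasis ->
# turnover
encode_day <- function(net, ensemble) {
  net$day <- net$day + 1L
  ep <- run_episode(net, ensemble, plasticity = TRUE)
  net <- update_tags(net, ep$calcium)
  net <- consolidate(net)
  net <- homeostasis(net, t_days = 1)
  net <- turnover_step(net)
  net
}

#' Encode one memory over consecutive daily episodes
#'
#' Each day: a 4-s stimulation episode of the memory's inputs, tagging from
#' episode calcium, PRP-capture consolidation, homeostatic scaling, and a
#' turnover step; state is carried across days.
#'
#' @param net an `stc_network`.
#' @param ensemble the memory's presynaptic input ids.
#' @param n_days encoding days (default 4).
#' @return the trained network.
#' @export
encode_memory <- function(net, ensemble, n_days = 4) {
  for (d in seq_len(n_days)) net <- encode_day(net, ensemble)
  net
}

#' Serially encode several memories and measure recall rates
#'
#' Memories are encoded one after another (`days_per_memory` daily episodes
#' each, 1-day inter-stimulus interval by construction); afterwards each
#' ensemble is re-activated with plasticity frozen and the excitatory firing
#' rates are recorded.
#'
#' @param net an `stc_network`.
#' @param memories list of input-id vectors (see [make_memories()]).
#' @param days_per_memory encoding days per memory.
#' @return list: `net` (final state), `recall` (matrix, neurons x memories,
#'   Hz).
#' @export
encode_serial <- function(net, memories, days_per_memory = 1) {
  for (m in memories) net <- encode_memory(net, m, n_days = days_per_memory)
  recall <- vapply(memories, function(m)
    run_episode(net, m, plasticity = FALSE)$rates, numeric(net$params$n_exc))
  list(net = net, recall = recall)
}
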