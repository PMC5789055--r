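---
title: "Spine turnover, clustered structural plasticity, and network function: methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Spine turnover, clustered structural plasticity, and network function: methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spineclust)
```

## Scope

`spineclust` implements the computational core of a longitudinal
dendritic-spine study: (i) the imaging statistics — turnover ratios,
clustering of newly formed spines under a 5 µm rule, nearest-neighbour
distances (NND), survival of clustered versus non-clustered spines, and
behavioural couplings; (ii) four Monte-Carlo / permutation null models that
calibrate those statistics against chance; (iii) a synthetic spine-map
generator so the whole chain is testable without in-vivo data; and (iv) a
biophysically inspired network simulator (integrate-and-fire somata with 20
dendritic subunits, synaptic tagging and capture, plasticity-related
proteins, homeostatic scaling, stochastic synaptic turnover) with engram
readouts.  The `analysis/` scripts chain these steps into a desk-scale
re-analysis; `scripts/acceptance.R` recomputes the headline quantities from
scratch.

## Imaging statistics

A **spine map** is one row per spine: animal, dendritic segment, a 1-D
position in µm along the segment (distances are measured base-to-base along
the shaft, so a segment is treated as a rectifiable 1-D curve and all
inter-spine distances are `|Δposition|`; distances are only defined within a
segment, never across branch points), and a 0/1 presence record per imaging
session.  Sessions are integer day labels relative to the first training
day; the canonical timeline is baseline imaging at days −3 and 0, training
through day 5, follow-up at day 35.

Fate classes derive purely from presence triples at `t_pre` (−3), `t0` (0)
and `t_end` (5):

* *turnover ratio* between two sessions = (formed + lost) / (n₁ + n₂),
  pooled over an animal's segments before dividing (counts are summed, not
  per-segment ratios averaged — the ratio is defined from summed counts, and
  pooling weights segments by their spine content);
* *new stable spines* are absent at day 0 and present at day 5; a spine that
  disappears and reappears is two events (presence is scored per session, no
  identity persists across gaps);
* *clustered spines* are new stable spines within d = 5 µm of another new
  stable spine on the same segment.  Clusters are connected components of
  the ≤ d adjacency graph (chaining allowed), because membership is a
  property of spines, not of pairs; components of size 1 are not clusters.
  The comparison is inclusive (≤ 5 µm) by default: the rule is quoted both
  ways in the literature and at floating-point resolution on continuous
  positions the difference has probability zero; `cluster_positions()`
  takes `inclusive = FALSE` for the strict variant.
* animals with fewer than 5 spines formed during learning are excluded from
  clustering ratios (the standard exclusion rule); the threshold is an
  argument everywhere it applies.
* *pre-learning turnover spines* are spines formed **or** lost between the
  two baseline sessions; both kinds mark turnover sites for the hotspot
  analyses.

The per-animal clustering percentage pools counts across segments before
dividing.  Whether to pool or to average per-segment ratios is genuinely
open; pooling was chosen to match the turnover-ratio convention and because
per-segment ratios are unstable at the 0–3 new spines a segment typically
carries.

`learning_rate()` implements the slope convention for freezing curves: the
asymptote is the chronologically first maximum before any decrease, and the
slope connects baseline (pre-shock) freezing to that asymptote.
`suppression_ratio()` is test / (baseline + test).  Group-level inference
(Mann-Whitney, Spearman) is left to base R's standard routines.

## Null models

All four nulls share one result type: R resampled statistic values, the
observed statistic, a moments-based Gaussian fit (μ = mean, σ = SD of the
resamples; reported for display parity with histogram figures), and an
add-one empirical p-value p = (1 + #at-least-as-extreme)/(R + 1).  The
empirical estimator, not the Gaussian tail, is authoritative: it is valid
for any null shape and cannot report p = 0.  One-sided direction defaults to
the side of the observed value relative to μ.  Every null is a pure function
of (map, parameters, seed); a single R RNG stream is seeded per call.

1. **Uniform-position clustering null** — per segment, the observed number
   of new stable spines is replaced by the same number of i.i.d. uniform
   positions on [0, L]; the per-animal clustering percentage is recomputed
   (same pooling, same exclusion rule) and averaged over animals.  No
   exclusion zone is imposed around existing spines.  On a single segment
   with two new spines the null mean has the closed form
   1 − (1 − d/L)², which the tests verify to Monte-Carlo error.
2. **Positional-permutation clustering null** — identical, except positions
   are drawn *without replacement* from the segment's ever-observed spine
   positions (new-spine identity is permuted over sites where spines are
   known to be able to exist).  Draws stay within a segment; positions are
   never swapped across segments.
3. **NND-to-turnover null** — turnover-spine positions are randomised
   (uniform, or positional as above) per segment; the distance from each
   clustered spine to the nearest randomised turnover position is averaged
   within animal, then across animals.  A clustered spine at mid-segment
   against one uniform turnover spine gives the closed form E|U − L/2| = L/4.
4. **Concordance null** — each segment is categorised by (turnover > 0,
   clusters > 0) into both / neither / turnover-only / clusters-only; the
   vector of clustered-spine counts is permuted across each animal's
   segments (turnover counts fixed) and the four percentages recomputed.
   Animals are averaged with equal weight, matching the construction of the
   other nulls; segment-weighted aggregation would let spine-rich animals
   dominate.  Animals with fewer than two segments carry no permutation
   information and are skipped with a warning.

## The synthetic generator

`generate_map()` emulates the statistical structure the analyses assume,
not the biology that produced it: per-animal baseline turnover
probabilities ρᵢ ~ N(0.10, 0.025) truncated to [0.05, 0.15] (the observed
per-animal range of baseline turnover, with wild-type cohort means around
8–12 %); Poisson baseline spines at 0.4 µm⁻¹ on ~40 µm segments, 8 segments
per animal, 17 animals; baseline loss with probability ρᵢ and matched
Poisson formation, which makes the realised turnover ratio concentrate on
ρᵢ; learning-phase additions at 0.03 µm⁻¹, each placed uniformly with
probability 1 − κ or within ± h of the segment's **hotspot** with
probability κ.  The hotspot is one randomly chosen prior-turnover site per
segment and learning phase: enrichment must concentrate additions at a
shared locus — if every spine drew its own turnover site, additions would
correlate with turnover but not with each other, and no excess clustering
could arise.  Follow-up survival is Bernoulli with probability 0.676 for
clustered and 0.49 for non-clustered new stable spines (the empirical
follow-up survival levels), applied *after* clustering is computed post hoc.
Defaults were fixed once so that chance-level clustering under the 5 µm rule
falls near 20–25 % (checked by simulation against the uniform null, never
asserted as ground truth), and κ = 0.8 for the trained condition, which places the cohort-mean observed clustering at ~42 % against a ~20 % chance level — the regime reported for trained animals.

Behaviour traces are monotone saturating freezing curves whose asymptote
rises with ρᵢ (gain 4 percentage points of freezing per percentage point of
turnover, Gaussian noise SD 6), so the positive turnover-learning
correlation is recoverable at n = 17 but not trivially strong.

What the generator does **not** emulate: imaging noise and scoring
ambiguity, within-animal segment heterogeneity beyond Poisson variation,
genotype biology (a mutant group is just a configuration with higher mean
ρᵢ), and any causal link from clustering to behaviour.  Passing tests
therefore show that the estimators recover the structure they assume — not
that real data contain it.

## The network model

Excitatory neurons are two-layer units: 20 independent dendritic subunits
feed a leaky integrate-and-fire soma with spike-rate adaptation.  Subunit
depolarisation decays with τ_b and receives impulse increments
w·E_syn/τ_b per presynaptic spike (the Dirac delta integrated across one
step); somatic voltage follows
C dV/dt = −g_L(V − E_L) − g_AHP(V − E_K) + I_syn, with
I_syn = g_syn·ΣV_b − IPSC, reset to E_L = 0 at threshold and
g_AHP ← g_AHP + a_AHP.  A somatic spike also sets a backpropagating
depolarisation E_bAP·e^(−t/τ_bAP) on all the neuron's subunits.  Calcium
enters a synapse on each presynaptic spike through an NMDA-like sigmoid of
the local depolarisation V_b + V_bAP centred at 30 mV (slope 5 mV), making
calcium a coincidence detector between presynaptic activity and somatic
firing.

Episode calcium sets synaptic tags (none / depotentiation / potentiation at
`ca_low` / `ca_high`) and raises the local PRP level to 1 above `theta_PRP`.
During the consolidation phase, a tagged synapse captures PRPs from all
synapses within 0.2 a.u. on its subunit (≈ 10 µm for a ~50 µm oblique
dendrite); the captured sum sets the consolidation rate.  Because every PRP
level decays with the same τ_PRP, the weight change over the phase has an
exact closed form (rate · P(0) · τ_PRP · (1 − e^(−T/τ_PRP))), applied
directly instead of a minutes-grid integration, then clipped to [0, 1].
Homeostatic scaling dw_j/dt = (1/τ_H)(1 − Σw_j/(w_init·N_syn)) is an
identical additive drift with fixed point Σw = w_init·N_syn; the total obeys
a linear ODE and is likewise advanced in closed form.  Daily turnover
removes synapses never potentiated beyond w_init = 0.2 with probability
(subunit rate)·Θ_removal — subunit rates are two-level, 0.1 or 1.0 — and
adds an equal number of fresh synapses (uniform subunit, uniform position,
random presynaptic source, weight w_init), conserving each neuron's synapse
count exactly.

Inhibition is named but not specified in the model definition; the package
uses a lumped feedback pool — IPSC proportional to a low-pass filter
(τ = 20 ms) of total excitatory spiking — which is the simplest mechanism
producing the winner-take-all competition that memory allocation requires.
Dendritic spike nonlinearities are likewise unspecified and are omitted;
subunit integration is linear.

### Parameters

Constants fixed by the model definition: E_L = 0 mV, w_init = 0.2,
potentiated means w > 0.8, capture radius 0.2 a.u., calcium sigmoid
(30 mV, 5 mV), 20 subunits, turnover rates 0.1/1.0, 4 s episodes, 4
consecutive encoding days for a single memory, 10 serially encoded memories
at 1-day intervals.  The full kinetic constant set is not available in the
extracted source, so the remaining values are package defaults in
`model_params()`, chosen once for functional behaviour and all
overridable:

| parameter | default | role |
|---|---|---|
| τ_b, E_syn | 20 ms, 60 mV | subunit kinetics; 0.2-weight spike ⇒ 0.6 mV |
| C, g_L, θ_soma | 1, 0.1, 10 mV | 10 ms membrane; threshold above rest |
| τ_AHP, a_AHP | 200 ms, 0.05 | adaptation strong enough to cap winner rates |
| E_bAP, τ_bAP | 40 mV, 15 ms | bAP briefly lifts V above the calcium midpoint |
| a_Ca, ca_low, ca_high, Θ_PRP | 1, 4, 8, 8 | tags need tens of coincident spikes |
| τ_PRP, rate, T | 60 min, 0.012/min, 180 min | full local PRP consolidates a tag to > 0.8 in one inter-episode interval |
| τ_H | 5 days | total-weight relaxation constant τ_H·w_init = 1 day |
| Θ_removal | 0.2 | high-turnover subunits replace ~20 % of eligible synapses per day |
| g_inh, τ_inh | 1/6 (30 neurons), 20 ms | competition: a minority of neurons wins each memory |
| population | 30 neurons × 200 synapses, 200 inputs, 20/ensemble at 50 Hz | smallest population with stable readouts |

The guiding constraints were mechanistic: (a) a synapse's calcium must
separate cleanly into no-tag / depotentiation / potentiation bands driven by
coincidence with somatic firing; (b) a fully tagged synapse with full local
PRP must reach the potentiated range within one between-episode interval;
(c) inhibition must allocate each memory to a minority of neurons while
leaving losers enough drive to compete for later memories.  Integration uses
fixed-step exponential-Euler at dt = 0.1 ms during episodes (spike-level
dynamics) and the closed forms above between episodes, where nothing spikes.

### Engram readouts

`clustered_pair_fraction()` counts same-subunit pairs of potentiated
(w > 0.8) synapses closer than 0.2 a.u., over all same-subunit pairs —
positions on different subunits share no coordinate system, so "all pairs"
is read as all same-subunit pairs; the pair-distance comparison is strict
(< radius).  `new_pair_fraction()` does the same for synapses born after
encoding day 1.  `treves_rolls_sparsity()` is (mean r)²/mean(r²) — 1 for
uniform rates, 1/N for a one-hot vector; the axis convention here follows
the source figures, where the plotted metric *rises* as turnover spreads
engram activity across the population.  `linear_trend()` provides the
one-way ANOVA plus the single-df equally-spaced-contrast post test for
linear trend used to summarise sweeps.

### Problem sizes

The packaged sweep uses 30 excitatory neurons × 200 synapses, five levels of
high-turnover subunit count {0, 5, 10, 15, 20} and 5 trials per level —
sizes chosen as the smallest at which the three trend readouts are stable
across seeds, and far below the original population-scale simulations.  At
this scale the trend *signs* and their significance reproduce; slope
magnitudes are not comparable to population-scale values and are not
asserted anywhere in the tests.

## Numerical and degenerate-input conventions

* Presence vectors must be 0/1 and never all-zero; positions must lie in
  [0, segment length]; violations are errors naming the row.
* Zero-denominator statistics (no spines at either session, empty cohort,
  all-zero rates, zero same-subunit pairs) are errors or per-animal NA with
  the animal dropped, never silent zeros.
* A zero-variance null with a discrepant observed value reports the floor
  p = 1/(R + 1) and is flagged `degenerate`.
* `linear_trend()` on a noise-free exact line reports p = 0 (F = ∞); on a
  constant response, slope 0 and p = 1.
* KS p-values are asymptotic (ties permitted; exact small-sample p is not
  used).
* Cluster ids are assigned in sorted-position order; ties (coincident
  positions) join the same cluster at any d ≥ 0.

## Known limitations

* The imaging statistics assume distances within a segment only; nothing is
  said or assumed about across-branch proximity.
* The simulator's inhibitory pool is a mean-field surrogate, not a spiking
  interneuron population, and subunit integration is linear (no dendritic
  spikes); both are extension points.
* The sparsity readout at 30 neurons is intrinsically noisy; the packaged
  trial counts bound, but do not eliminate, seed-to-seed variation in its
  trend p-value.
* Synthetic data validate estimator correctness and power, not biological
  truth; effect sizes in real cohorts may sit anywhere relative to the
  generator's defaults.
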