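# spineclust

Tools for asking how dendritic spine turnover shapes learning-related
clustered structural plasticity — and what that clustering does to network
function.  The package is written for researchers analysing longitudinal
two-photon spine-imaging data (per-segment spine positions scored for
presence across imaging days) and for modellers studying memory allocation
with synaptic tagging and capture.

It provides three things:

1. **Imaging statistics.**  Turnover ratio between sessions
   (formed + lost)/(n₁ + n₂); clustering of newly formed stable spines under
   the 5 µm rule (clusters are transitive groups of ≥ 2 new spines within
   d of each other on a segment); nearest-neighbour distances between fate
   classes with a two-sample KS test; survival of clustered vs non-clustered
   spines at follow-up; per-segment turnover/clustering densities; and the
   behavioural metrics (learning-rate slope of a freezing curve, activity
   suppression ratio).
2. **Null models.**  Four seeded Monte-Carlo/permutation nulls returning a
   Gaussian fit of the resampled statistic and an add-one empirical p-value:
   uniform-position and positional-permutation nulls for the clustering
   percentage, randomised-turnover-position nulls for the clustered-spine to
   turnover-site NND, and a within-animal permutation of clustered-spine
   counts across segments (concordance categories).
3. **A network model.**  Two-layer excitatory neurons (leaky
   integrate-and-fire soma with adaptation over 20 dendritic subunits,
   τ_b dV_b/dt = Σ wE_syn δ(t−t_ij) − V_b), NMDA-like calcium per
   presynaptic spike (sigmoid of V_b + V_bAP centred at 30 mV), synaptic
   tags consolidated by captured plasticity-related proteins within a
   0.2 a.u. radius, homeostatic weight scaling, and daily stochastic
   turnover that replaces non-potentiated synapses.  Readouts: same-subunit
   potentiated-pair and new-pair clustering fractions and the Treves-Rolls
   population sparsity a = (Σrᵢ/N)²/(Σrᵢ²/N), with a one-way ANOVA +
   linear-trend post test over a sweep of high-turnover subunit counts.

A synthetic spine-map generator (`generate_map()`) reproduces the
statistical structure the analyses assume — per-animal baseline turnover
probabilities, hotspot-enriched spine addition, survival differences — so
the entire chain runs and is tested without animal data.  See the methods
vignette (`vignettes/spine-turnover-clustering.Rmd`) for the model details
and every default.

## Worked example

```r
library(spineclust)

# a synthetic trained cohort: 17 animals, hotspot enrichment kappa = 0.8
g <- generate_map(generator_config(), seed = 7)
map <- g$map

cluster_new_spines(map)$mean_ratio * 100
#> [1] 45.6          # % of new stable spines in clusters, mean over animals

nu <- null_cluster_uniform(map, R = 2000, seed = 1)
nu
#> <null_distribution> clustering ratio (uniform-position null) | R = 2000
#>   observed = 0.4561 | Gaussian fit mu = 0.2354, sigma = 0.04186
#>   empirical p (one-sided, greater) = 0.0004998
```

The observed clustering (45.6 %) sits far above the chance level implied by
uniformly repositioned new spines (23.5 % for this map), with an empirical
p of 5e-4 — the hotspot enrichment is detected.  The same map yields
hotspot proximity (mean clustered-spine-to-turnover NND 1.6 µm vs 6.5 µm
under the null) and a clustered-spine survival advantage at follow-up
(68 % vs 47 %):

```r
nn <- null_nnd_turnover(map, "uniform", R = 1000, seed = 2)
sv <- survival_rate(map, t_follow = 35)
colMeans(sv[, 4:5], na.rm = TRUE)
#> survival_clustered survival_nonclustered
#>              0.68                  0.47
```

On the modelling side:

```r
sw <- run_turnover_sweep(model_params(), n_trials = 5, seed = 42)
linear_trend(sw$n_high, sw$sparsity)[c("slope", "p_trend")]
#> $slope  0.0018     # sparsity metric rises with high-turnover subunits
#> $p_trend 0.0020    # (about two minutes: 25 serial-encoding runs)
```

## The analysis workflow

`analysis/01_generate_data.R` … `04_network_simulation.R` run the full
desk-scale study: cohort generation, imaging statistics, the four nulls,
and the turnover sweep.  Each writes tidy CSVs plus a JSON run manifest
under `results/`.

```sh
Rscript analysis/01_generate_data.R
Rscript analysis/02_spine_statistics.R
Rscript analysis/03_null_models.R
Rscript analysis/04_network_simulation.R
```

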