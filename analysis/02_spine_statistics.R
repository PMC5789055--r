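#!/usr/bin/env Rscript

# Step 2: imaging statistics on the generated cohorts.
#
# Per-animal baseline turnover ratios, clustering ratios of newly added
# stable spines (5-um rule, <5-formed exclusion), gained-spine
# nearest-neighbour distances with the trained-vs-control KS test,
# clustered vs non-clustered survival at follow-up, per-segment
# turnover/clustering densities, and the behavioural couplings
# (turnover vs mean freezing, learning-rate slopes).

library(spineclust)

seed <- 20260925L

load_cohort <- function(tag) {
  map <- read_spine_table(sprintf("results/spines_%s.csv", tag),
                          behavior_path = sprintf("results/behavior_%s.csv", tag))
  annotate_fates(map, -3, 0, 5)
}
trained <- load_cohort("trained")
control <- load_cohort("control")

## turnover and clustering per animal
tr_t <- turnover_ratio(trained, -3, 0)
cl_t <- cluster_new_spines(trained)
cl_c <- cluster_new_spines(control)
per_animal <- merge(tr_t, cl_t$by_animal, by = "animal")
write.csv(per_animal, "results/per_animal_trained.csv", row.names = FALSE)

cat(sprintf("mean clustering: trained %.1f%% vs control %.1f%%\n",
            100 * cl_t$mean_ratio, 100 * cl_c$mean_ratio))

## gained-spine NND distributions and KS shift
nnd_t <- nnd_new_spines(trained)
nnd_c <- nnd_new_spines(control)
ks <- ks_two_sample(nnd_t$distance, nnd_c$distance)
cat(sprintf("gained-spine NND: trained n=%d, control n=%d, KS D=%.3f p=%.2g\n",
            nrow(nnd_t), nrow(nnd_c), ks$D, ks$p))

## survival of clustered vs non-clustered spines at day 35
sv <- survival_rate(trained, 35)
write.csv(sv, "results/survival_trained.csv", row.names = FALSE)
cat(sprintf("survival at follow-up: clustered %.1f%% vs non-clustered %.1f%%\n",
            100 * mean(sv$survival_clustered, na.rm = TRUE),
            100 * mean(sv$survival_nonclustered, na.rm = TRUE)))

## per-segment densities (hotspot structure at the segment level)
dens <- segment_densities(trained)
write.csv(dens, "results/segment_densities_trained.csv", row.names = FALSE)
rho_seg <- cor(dens$turnover_density, dens$cluster_density, method = "spearman")
cat(sprintf("segment-level turnover vs clustering density: Spearman rho = %.2f (n=%d segments)\n",
            rho_seg, nrow(dens)))

## behaviour: turnover vs freezing, learning rates, suppression
beh <- trained$behavior
mf <- tapply(beh$freezing[beh$day >= 2], beh$animal[beh$day >= 2], mean)
rho_beh <- cor(tr_t$ratio, mf[tr_t$animal], method = "spearman")
cat(sprintf("baseline turnover vs mean freezing (days 2-5): Spearman rho = %.2f\n",
            rho_beh))

lr <- vapply(split(beh, beh$animal), function(b)
  learning_rate(b$day, b$freezing), numeric(1))
supp <- vapply(split(beh, beh$animal), function(b)
  suppression_ratio(mean(b$freezing[b$day >= 2]), b$freezing[b$day == 0]),
  numeric(1))
behav <- data.frame(animal = names(lr), learning_rate = lr,
                    suppression_ratio = supp, mean_freezing = mf[names(lr)])
write.csv(behav, "results/behavior_metrics_trained.csv", row.names = FALSE)

write_run_manifest("results/02_spine_statistics.manifest.json",
                   step = "spine_statistics", seed = seed,
                   parameters = list(d_um = 5, min_formed = 5,
                                     t_pre = -3, t0 = 0, t_end = 5,
                                     t_follow = 35),
                   outputs = c("results/per_animal_trained.csv",
                               "results/survival_trained.csv",
                               "results/segment_densities_trained.csv",
                               "results/behavior_metrics_trained.csv"))
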