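test_that("turnover ratio matches its count-based definition", {
  # 10 spines at day -3 and at day 0; 1 lost, 1 formed -> (1+1)/(10+10)
  map <- seg_map(position = seq(2, 42, by = 4),
                 presence = c(rep("11110", 9), "10000", "01110"))
  tr <- turnover_ratio(map, -3, 0)
  expect_equal(tr$n_formed, 1L); expect_equal(tr$n_lost, 1L)
  expect_equal(tr$n_t1, 10L); expect_equal(tr$n_t2, 10L)
  expect_equal(tr$ratio, 0.10)

  none <- seg_map(position = c(5, 10), presence = c("11110", "11110"))
  expect_equal(turnover_ratio(none, -3, 0)$ratio, 0)

  # full replacement: 5 lost, 5 formed
  full <- seg_map(position = seq(1, 46, by = 5),
                  presence = c(rep("10000", 5), rep("01110", 5)))
  expect_equal(turnover_ratio(full, -3, 0)$ratio, 1.0)
})

test_that("clustering is the transitive closure of the distance rule", {
  ids <- cluster_positions(c(1, 3, 20), d = 5)
  expect_equal(ids > 0, c(TRUE, TRUE, FALSE))     # pair {1,3}; 20 is singleton

  expect_equal(cluster_positions(7, d = 5), 0L)   # no pair possible

  chain <- cluster_positions(c(0, 4, 8), d = 5)   # 0-4 and 4-8 adjacent: one cluster
  expect_equal(chain, c(1L, 1L, 1L))

  map <- annotated(seg_map(position = c(1, 3, 20),
                           presence = rep("00110", 3)))
  cl <- cluster_new_spines(map, d = 5, min_formed = 0)
  expect_equal(cl$by_animal$clustering_ratio, 2 / 3)

  single <- annotated(seg_map(position = 7, presence = "00110"))
  expect_equal(cluster_new_spines(single, min_formed = 0)$by_animal$clustering_ratio, 0)
})

test_that("clustering and turnover ratios are invariant to relabeling and reflection", {
  g <- generate_map(generator_config(n_animals = 4), seed = 3)
  map <- g$map
  cl <- cluster_new_spines(map)
  tr <- turnover_ratio(map, -3, 0)

  refl <- map$spines
  refl$position <- refl$segment_length - refl$position
  refl$segment <- paste0("x", refl$segment)       # relabel segments too
  map2 <- annotate_fates(spine_map(refl), -3, 0, 5)
  expect_equal(cluster_new_spines(map2)$by_animal$clustering_ratio,
               cl$by_animal$clustering_ratio)
  expect_equal(turnover_ratio(map2, -3, 0)$ratio, tr$ratio)
})

test_that("edge thresholds: d = 0 needs coincident positions; huge d clusters everything", {
  expect_equal(cluster_positions(c(1, 3, 20), d = 0), rep(0L, 3))
  expect_equal(cluster_positions(c(5, 5, 20), d = 0)[1:2], c(1L, 1L))
  expect_true(all(cluster_positions(c(1, 3, 20), d = 1000) == 1L))
})

test_that("nearest-neighbour distances are per-source minima", {
  expect_equal(sort(nnd_1d(c(0, 4, 12), c(0, 4, 12), self = TRUE)), c(4, 4, 8))
  expect_equal(nnd_1d(numeric(0), c(1, 2)), numeric(0))
  expect_equal(nnd_1d(10, c(7, 30)), 3)

  map <- annotated(seg_map(position = c(0, 4, 12),
                           presence = rep("00110", 3)))
  expect_equal(sort(nnd_new_spines(map)$distance), c(4, 4, 8))

  # lost spine at 10; gained at 7 (clustered with 5) and 30 (not)
  lmap <- annotated(seg_map(position = c(10, 5, 7, 30),
                            presence = c("11000", "00110", "00110", "00110")))
  lg <- nnd_lost_to_gained(lmap)
  expect_equal(lg$distance, 3)
  expect_true(lg$neighbor_clustered)
})

test_that("KS statistic agrees with an explicit ECDF enumeration", {
  expect_equal(ks_two_sample(c(1, 2, 3), c(1, 2, 3))$D, 0)
  expect_equal(ks_two_sample(c(1, 2, 3), c(10, 11))$D, 1)

  # independent oracle: evaluate both ECDFs over the pooled support
  ks_oracle <- function(x, y) {
    grid <- sort(unique(c(x, y)))
    max(abs(vapply(grid, function(g) mean(x <= g) - mean(y <= g), numeric(1))))
  }
  x <- c(1, 2, 3); y <- c(2, 3, 4)
  expect_equal(ks_two_sample(x, y)$D, ks_oracle(x, y))
  expect_equal(ks_oracle(x, y), 1 / 3)

  set.seed(1)
  for (i in 1:5) {
    a <- rnorm(20); b <- rnorm(15, 0.5)
    expect_equal(ks_two_sample(a, b)$D, ks_oracle(a, b))
    # D is invariant under a common monotone transform
    expect_equal(ks_two_sample(exp(a), exp(b))$D, ks_two_sample(a, b)$D)
  }
  expect_error(ks_two_sample(numeric(0), 1), "non-empty")
})

test_that("survival partitions the new-stable cohort by clustered status", {
  # clustered pair {2,5} (one survives to d35), non-clustered {20,40} (none survive)
  map <- annotated(seg_map(
    position = c(2, 5, 20, 40),
    presence = c("00111", "00110", "00110", "00110")))
  sv <- survival_rate(map, 35, min_formed = 0)
  expect_equal(sv$survival_clustered, 0.5)
  expect_equal(sv$survival_nonclustered, 0)

  all_live <- annotated(seg_map(position = c(2, 5),
                                presence = c("00111", "00111")))
  expect_equal(survival_rate(all_live, 35, min_formed = 0)$survival_clustered, 1.0)

  # the union survival is the count-weighted mean of the sub-cohorts
  g <- generate_map(generator_config(n_animals = 3), seed = 9)
  sv2 <- survival_rate(g$map, 35, min_formed = 0)
  new <- cluster_new_spines(g$map, min_formed = 0)$spines
  alive <- presence_at_follow <- g$map$spines$d35[match(new$spine_id, g$map$spines$spine_id)]
  for (i in seq_len(nrow(sv2))) {
    a <- sv2$animal[i]
    pooled <- mean(alive[new$animal == a] == 1)
    parts <- c(sv2$survival_clustered[i], sv2$survival_nonclustered[i])
    wts <- c(sv2$n_clustered[i], sv2$n_nonclustered[i])
    expect_equal(sum(parts * wts, na.rm = TRUE) / sum(wts), pooled)
  }
})

test_that("segment densities normalise counts by length", {
  map <- annotated(seg_map(position = c(10, 30, 1, 4, 20),
                           presence = c("10000", "01110",      # 2 turnover events
                                        "00110", "00110", "11110"),
                           length = 40))
  d <- segment_densities(map)
  expect_equal(d$turnover_density, 2 / 40)
  expect_equal(d$n_clustered, 2L)                 # pair {1,4}
  expect_equal(d$cluster_density, 2 / 40)

  quiet <- annotated(seg_map(position = c(10, 30), length = 30,
                             presence = c("11110", "11110")))
  dq <- segment_densities(quiet)
  expect_equal(dq$turnover_density, 0)
  expect_equal(dq$cluster_density, 0)
})

test_that("learning rate uses the first pre-decrease maximum as asymptote", {
  expect_equal(learning_rate(0:4, c(10, 25, 40, 55, 60)), (60 - 10) / 4)
  expect_equal(learning_rate(0:4, rep(20, 5)), 0)
  # rises to 50 % on day 2 then falls: asymptote day 2
  expect_equal(learning_rate(0:4, c(10, 30, 50, 40, 45)), (50 - 10) / 2)
  expect_error(learning_rate(0, 10), "baseline")
})

test_that("suppression ratio is test / (baseline + test)", {
  expect_equal(suppression_ratio(0, 5), 0)
  expect_equal(suppression_ratio(3, 3), 0.5)
  expect_equal(suppression_ratio(2, 6), 0.25)
  expect_error(suppression_ratio(0, 0), "undefined")
})
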