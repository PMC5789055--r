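test_that("null summaries use the moments fit and the add-one empirical p", {
  vals <- c(1:99, 1000) / 10
  s <- summarize_null(vals, observed = median(vals), sidedness = "one")
  expect_equal(s$gaussian_mu, mean(vals))
  expect_equal(s$gaussian_sigma, sd(vals))
  expect_gt(s$p_empirical, 0.4); expect_lt(s$p_empirical, 0.6)

  beyond <- summarize_null(seq_len(10000) / 10000, observed = 2,
                           sidedness = "one")
  expect_equal(beyond$p_empirical, 1 / 10001)

  flat <- summarize_null(rep(5, 100), observed = 5, sidedness = "one")
  expect_equal(flat$p_empirical, 1.0)

  degen <- summarize_null(rep(5, 100), observed = 7, sidedness = "one")
  expect_equal(degen$p_empirical, 1 / 101)
  expect_true(degen$degenerate)
})

test_that("uniform-position null matches the closed form for two spines", {
  # P(|U1 - U2| <= d) = 1 - (1 - d/L)^2 for two uniforms on [0, L]
  map <- annotated(seg_map(position = c(10, 30), length = 50,
                           presence = c("00110", "00110")))
  nu <- null_cluster_uniform(map, d = 5, R = 4000, seed = 1, min_formed = 0)
  closed <- 1 - (1 - 5 / 50)^2
  se <- sd(nu$values) / sqrt(nu$R)
  expect_lt(abs(nu$gaussian_mu - closed), 3 * se)
  expect_true(all(nu$values >= 0 & nu$values <= 1))
})

test_that("degenerate geometries give the exact null value", {
  # a lone new spine can never cluster
  lone <- annotated(seg_map(position = c(10, 30), length = 50,
                            presence = c("00110", "11110")))
  nu <- null_cluster_uniform(lone, R = 50, seed = 1, min_formed = 0)
  expect_true(all(nu$values == 0))

  # threshold wider than the segment: everything clusters
  tight <- annotated(seg_map(position = c(10, 30), length = 50,
                             presence = c("00110", "00110")))
  nu2 <- null_cluster_uniform(tight, d = 60, R = 50, seed = 1, min_formed = 0)
  expect_true(all(nu2$values == 1))
})

test_that("positional null matches exhaustive pair enumeration", {
  # candidates {0, 2, 20, 40}; two are new -> C(4,2) = 6 equally likely pairs
  map <- annotated(seg_map(position = c(0, 2, 20, 40), length = 50,
                           presence = c("00110", "00110", "11110", "11110")))
  nu <- null_cluster_positional(map, d = 5, R = 4000, seed = 2, min_formed = 0)
  pairs <- combn(c(0, 2, 20, 40), 2)
  frac <- apply(pairs, 2, function(p) mean(cluster_positions(p, 5) > 0))
  oracle <- mean(frac)
  expect_equal(oracle, 1 / 6)
  se <- sd(nu$values) / sqrt(nu$R)
  expect_lt(abs(nu$gaussian_mu - oracle), 3 * se)

  # all candidates within d: clustering certain
  all_close <- annotated(seg_map(position = c(0, 2, 4), length = 50,
                                 presence = c("00110", "00110", "11110")))
  nu3 <- null_cluster_positional(all_close, d = 5, R = 50, seed = 3,
                                 min_formed = 0)
  expect_true(all(nu3$values == 1))
})

test_that("NND-to-turnover null matches E|U - L/2| = L/4", {
  # two coincident clustered spines at L/2; one turnover spine randomised
  L <- 50
  map <- annotated(seg_map(position = c(L / 2, L / 2, 40), length = L,
                           presence = c("00110", "00110", "10000")))
  nn <- null_nnd_turnover(map, "uniform", R = 4000, seed = 4, min_formed = 0)
  se <- sd(nn$values) / sqrt(nn$R)
  expect_lt(abs(nn$gaussian_mu - L / 4), 3 * se)
  expect_equal(nn$observed, abs(25 - 40))

  # positional variant with all candidate positions coincident: NND always 0
  cmap <- annotated(seg_map(position = c(10, 10, 10), length = L,
                            presence = c("00110", "00110", "10000")))
  nn0 <- null_nnd_turnover(cmap, "positional", R = 50, seed = 5,
                           min_formed = 0)
  expect_true(all(nn0$values == 0))
})

test_that("concordance null matches enumeration over segment permutations", {
  # 3 segments; cluster counts (2,0,0), turnover counts (1,0,0)
  df <- data.frame(
    animal = "a1",
    segment = rep(c("s1", "s2", "s3"), times = c(4, 2, 2)),
    length = 50,
    position = c(10, 1, 3, 30,   5, 25,   5, 25),
    presence = c("10000", "00110", "00110", "11110",
                 "11110", "11110", "11110", "11110"),
    stringsAsFactors = FALSE)
  map <- annotated(build_map(df))
  co <- null_concordance(map, R = 4000, seed = 6)

  # enumeration: the nonzero cluster count lands on each segment equally often
  cat_pct <- function(turn, clus)
    c(mean(turn > 0 & clus > 0), mean(turn == 0 & clus == 0),
      mean(turn > 0 & clus == 0), mean(turn == 0 & clus > 0)) * 100
  placements <- list(c(2, 0, 0), c(0, 2, 0), c(0, 0, 2))
  oracle <- rowMeans(vapply(placements, function(cl)
    cat_pct(c(1, 0, 0), cl), numeric(4)))
  for (i in seq_along(co)) {
    se <- sd(co[[i]]$values) / sqrt(co[[i]]$R)
    expect_lt(abs(co[[i]]$gaussian_mu - oracle[i]), 3 * se + 1e-9)
  }

  # every segment "both": permutation-invariant at 100 %
  df2 <- data.frame(animal = "a1", segment = rep(c("s1", "s2"), each = 3),
                    length = 50, position = c(10, 1, 3, 30, 21, 23),
                    presence = rep(c("10000", "00110", "00110"), 2),
                    stringsAsFactors = FALSE)
  co2 <- null_concordance(annotated(build_map(df2)), R = 100, seed = 7)
  expect_true(all(co2$both$values == 100))
})

test_that("null distributions are a pure function of inputs and seed", {
  g <- generate_map(generator_config(n_animals = 4), seed = 13)
  a <- null_cluster_uniform(g$map, R = 200, seed = 42)
  b <- null_cluster_uniform(g$map, R = 200, seed = 42)
  expect_identical(a$values, b$values)
  c1 <- null_nnd_turnover(g$map, "positional", R = 100, seed = 7, min_formed = 0)
  c2 <- null_nnd_turnover(g$map, "positional", R = 100, seed = 7, min_formed = 0)
  expect_identical(c1$values, c2$values)
})
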