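#' Fraction of same-subunit synapse pairs that are clustered and potentiated
#'
#' Numerator: pairs of potentiated synapses (w > `w_thresh`) on the same
#' dendritic subunit whose positions differ by less than `radius` a.u.
#' Denominator: all same-subunit synapse pairs (positions share a coordinate
#' system only within a subunit).  Aggregated over all neurons.
#'
#' @param net an `stc_network`.
#' @param w_thresh potentiation threshold (default 0.8).
#' @param radius clustering radius in a.u. (default 0.2); comparison is
#'   strict (`< radius`).
#' @return fraction in \[0, 1\].
#' @export
clustered_pair_fraction <- function(net, w_thresh = 0.8, radius = 0.2) {
  syn <- net$syn
  pair_counts(syn, syn$w > w_thresh, radius)
}

#' Fraction of same-subunit pairs that are clustered new synapses
#'
#' New synapses are those added after the first simulated encoding day
#' (birth day > `birth_cutoff`).  Numerator: same-subunit pairs of new
#' synapses within `radius`; denominator: all same-subunit pairs.
#'
#' @param net an `stc_network`.
#' @param birth_cutoff day threshold (default 1: added after day 1).
#' @param radius clustering radius in a.u.
#' @return fraction in \[0, 1\].
#' @export
new_pair_fraction <- function(net, birth_cutoff = 1, radius = 0.2) {
  syn <- net$syn
  pair_counts(syn, syn$birth > birth_cutoff, radius)
}

# shared pair enumeration: fraction of all same-subunit pairs for which both
# members satisfy `flag` and |dpos| < radius
pair_counts <- function(syn, flag, radius) {
  key <- paste(syn$neuron, syn$subunit, sep = "\r")
  total <- 0; clustered <- 0
  for (k in unique(key)) {
    i <- which(key == k)
    n <- length(i)
    if (n < 2L) next
    total <- total + n * (n - 1) / 2
    j <- i[flag[i]]
    if (length(j) >= 2L) {
      dmat <- abs(outer(syn$pos[j], syn$pos[j], "-"))
      clustered <- clustered + sum(dmat[upper.tri(dmat)] < radius)
    }
  }
  if (total == 0) stop("no same-subunit synapse pairs: fraction undefined")
  clustered / total
}

#' Treves-Rolls population sparsity
#'
#' a = (sum r_i / N)^2 / (sum r_i^2 / N): 1 for uniform rates, 1/N when a
#' single neuron is active; invariant to scaling all rates by a positive
#' constant.  Lower values indicate sparser activity.
#'
#' @param rates nonnegative firing rates.
#' @return a in (0, 1\].
#' @export
treves_rolls_sparsity <- function(rates) {
  if (any(rates < 0)) stop("rates must be nonnegative")
  if (all(rates == 0)) stop("sparsity undefined for an all-zero rate vector")
  mean(rates)^2 / mean(rates^2)
}

#' One-way ANOVA with a post test for linear trend
#'
#' Across ordered group levels x: the one-way ANOVA F, plus the post test
#' for linear trend computed as a single-degree-of-freedom contrast with
#' equally spaced (centred level) coefficients against the within-group mean
#' square.  The slope is the least-squares regression of y on x.
#'
#' @param x numeric level of each observation (>= 3 distinct levels).
#' @param y response values (>= 2 per level).
#' @return list: `slope`, `r_squared`, `F_anova`, `p_anova`, `F_trend`,
#'   `p_trend`.
#' @export
linear_trend <- function(x, y) {
  stopifnot(length(x) == length(y))
  levels_x <- sort(unique(x))
  if (length(levels_x) < 3L) stop("need at least 3 levels")
  n_i <- table(factor(x, levels = levels_x))
  if (any(n_i < 2L)) stop("need at least 2 values per level")
  fit_aov <- aov(y ~ factor(x))
  # perfect fits are handled explicitly below; silence the F-test caveat
  tab <- suppressWarnings(anova(fit_aov))
  ms_within <- tab["Residuals", "Mean Sq"]
  df_within <- tab["Residuals", "Df"]
  # linear-trend contrast with centred level coefficients
  cc <- levels_x - mean(levels_x)
  ybar <- tapply(y, factor(x, levels = levels_x), mean)
  L <- sum(cc * ybar)
  ss_trend <- L^2 / sum(cc^2 / as.numeric(n_i))
  if (ms_within == 0 && ss_trend == 0) {
    # constant response: no trend
    F_trend <- 0; p_trend <- 1
  } else if (ms_within == 0) {
    # noise-free separation: the trend is exact
    F_trend <- Inf; p_trend <- 0
  } else {
    F_trend <- ss_trend / ms_within
    p_trend <- pf(F_trend, 1, df_within, lower.tail = FALSE)
  }
  fit_lm <- lm(y ~ x)
  list(slope = unname(coef(fit_lm)[2]),
       r_squared = suppressWarnings(summary(fit_lm)$r.squared),
       F_anova = tab[1, "F value"], p_anova = tab[1, "Pr(>F)"],
       F_trend = F_trend, p_trend = p_trend)
}

#' Sweep the number of high-turnover subunits and collect engram readouts
#'
#' For each level of `n_high` and each trial: (1) a fresh network encodes a
#' single memory over `n_days` daily episodes, and the potentiated-pair and
#' new-synapse-pair clustering fractions are measured; (2) a second fresh
#' network serially encodes `n_memories` memories (1 day each), each memory
#' is recalled with plasticity frozen, and the mean Treves-Rolls sparsity
#' over memories is recorded.
#'
#' @param params a [model_params()].
#' @param n_high_levels numbers of high-turnover subunits to sweep.
#' @param n_trials trials per level.
#' @param seed RNG seed.
#' @param n_days encoding days for the single-memory runs.
#' @param n_memories serially encoded memories for the sparsity runs.
#' @return data.frame: `n_high`, `trial`, `clustered_pair_pct`,
#'   `new_pair_pct`, `sparsity`.
#' @export
run_turnover_sweep <- function(params = model_params(),
                               n_high_levels = c(0, 5, 10, 15, 20),
                               n_trials = 5, seed = 1,
                               n_days = 4, n_memories = 10) {
  set.seed(seed)
  rows <- list()
  for (nh in n_high_levels) {
    for (tr in seq_len(n_trials)) {
      net <- new_network(params, n_high_turnover = nh)
      mem <- make_memories(params, 1)[[1]]
      net <- encode_memory(net, mem, n_days = n_days)
      cpf <- clustered_pair_fraction(net, params$w_potentiated,
                                     params$capture_radius)
      npf <- new_pair_fraction(net, birth_cutoff = 1,
                               radius = params$capture_radius)

      net2 <- new_network(params, n_high_turnover = nh)
      mems <- make_memories(params, n_memories)
      ser <- encode_serial(net2, mems, days_per_memory = 1)
      a <- apply(ser$recall, 2, function(r)
        if (all(r == 0)) NA_real_ else treves_rolls_sparsity(r))
      rows[[length(rows) + 1L]] <- data.frame(
        n_high = nh, trial = tr,
        clustered_pair_pct = 100 * cpf, new_pair_pct = 100 * npf,
        sparsity = mean(a, na.rm = TRUE))
    }
  }
  do.call(rbind, rows)
}
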