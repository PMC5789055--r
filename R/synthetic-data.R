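#' Configuration for the synthetic spine-map generator
#'
#' The generator emulates the statistical structure of longitudinal spine
#' imaging over a contextual-learning timeline: per-animal variability in
#' baseline turnover, learning-phase spine addition with optional hotspot
#' enrichment near prior-turnover sites, chance-level clustering around
#' 20-25 % under the 5-micron rule when enrichment is off, and differential
#' follow-up survival of clustered vs non-clustered spines.
#'
#' @param n_animals number of animals.
#' @param n_segments dendritic segments per animal.
#' @param segment_length_mean,segment_length_sd segment length distribution
#'   (micrometres; normal, floored at 15).
#' @param baseline_density baseline spine density (spines per micrometre).
#' @param rho_mean,rho_sd per-animal baseline turnover probability rho_i
#'   (normal, truncated to `rho_range`).
#' @param rho_range allowed range of rho_i.
#' @param new_rate learning-phase spine additions per micrometre.
#' @param kappa hotspot enrichment: probability a new spine is placed within
#'   `h` of a prior-turnover site instead of uniformly (0 = uniform).
#' @param h hotspot radius (micrometres).
#' @param cluster_threshold clustering rule threshold d (micrometres).
#' @param p_stable probability a learning-formed spine is still present at
#'   the end of learning (enters the new-stable pool).
#' @param surv_clustered,surv_nonclustered follow-up survival probabilities
#'   of clustered / non-clustered new stable spines.
#' @param p_baseline_follow follow-up presence probability of baseline-stable
#'   spines.
#' @param schedule imaging-session day labels (baseline, day 0, training
#'   days, follow-up).
#' @param t_pre,t0,t_end,t_follow named sessions used by the analyses.
#' @param group,genotype labels stamped on every animal.
#' @param freeze_baseline_mean,freeze_gain,freeze_noise_sd,freeze_tau
#'   behaviour model: freezing(day) saturates from baseline towards an
#'   asymptote `freeze_baseline_mean + freeze_gain * 100 * rho_i`, with time
#'   constant `freeze_tau` days and Gaussian noise.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(n_animals = 17,
                             n_segments = 8,
                             segment_length_mean = 40,
                             segment_length_sd = 10,
                             baseline_density = 0.4,
                             rho_mean = 0.10,
                             rho_sd = 0.025,
                             rho_range = c(0.05, 0.15),
                             new_rate = 0.03,
                             kappa = 0.8,
                             h = 5,
                             cluster_threshold = 5,
                             p_stable = 0.85,
                             surv_clustered = 0.676,
                             surv_nonclustered = 0.49,
                             p_baseline_follow = 0.9,
                             schedule = c(-3, 0, 2, 5, 35),
                             t_pre = -3, t0 = 0, t_end = 5, t_follow = 35,
                             group = "trained", genotype = "WT",
                             freeze_baseline_mean = 10,
                             freeze_gain = 4,
                             freeze_noise_sd = 6,
                             freeze_tau = 1.5) {
  cfg <- as.list(environment())
  stopifnot(cfg$kappa >= 0, cfg$kappa <= 1, cfg$h > 0,
            cfg$baseline_density > 0, cfg$new_rate > 0,
            all(diff(cfg$schedule) > 0),
            all(c(t_pre, t0, t_end, t_follow) %in% schedule))
  probs <- c(cfg$p_stable, cfg$surv_clustered, cfg$surv_nonclustered,
             cfg$p_baseline_follow)
  stopifnot(all(probs >= 0 & probs <= 1))
  if (cfg$h > cfg$segment_length_mean + 4 * cfg$segment_length_sd) {
    stop("hotspot radius h exceeds plausible segment lengths")
  }
  class(cfg) <- "generator_config"
  cfg
}

rtrunc_norm <- function(n, mean, sd, lo, hi) {
  pmin(pmax(rnorm(n, mean, sd), lo), hi)
}

#' Generate a synthetic spine map
#'
#' Baseline spines are Poisson along each segment; the baseline session pair
#' realises per-spine loss with probability rho_i and matched Poisson
#' formation; a matching fraction of surviving baseline spines is lost again
#' during learning (turnover continues through training); learning-phase
#' additions are placed uniformly with probability 1 - kappa or within
#' +/- h of a random prior-turnover site with probability kappa (clipped to
#' the segment); presence at the end of learning is Bernoulli(p_stable);
#' follow-up survival is Bernoulli by post-hoc clustered status under the
#' `cluster_threshold` rule.
#'
#' @param config a [generator_config()].
#' @param seed RNG seed; the result is a pure function of (config, seed).
#' @return list: `map` (a `spine_map`, behaviour attached), `truth`
#'   (per-spine ground-truth event table), `rho` (named per-animal turnover
#'   probabilities).
#' @export
generate_map <- function(config = generator_config(), seed = 1) {
  stopifnot(inherits(config, "generator_config"))
  set.seed(seed)
  cfg <- config
  days <- cfg$schedule
  nd <- length(days)
  i_pre <- match(cfg$t_pre, days); i0 <- match(cfg$t0, days)
  i_end <- match(cfg$t_end, days); i_fol <- match(cfg$t_follow, days)
  training_days <- days[days > cfg$t0 & days <= cfg$t_end]
  rho <- setNames(rtrunc_norm(cfg$n_animals, cfg$rho_mean, cfg$rho_sd,
                              cfg$rho_range[1], cfg$rho_range[2]),
                  sprintf("animal%02d", seq_len(cfg$n_animals)))

  seg_frames <- list()
  for (a in names(rho)) {
    for (s in seq_len(cfg$n_segments)) {
      L <- max(15, rnorm(1, cfg$segment_length_mean, cfg$segment_length_sd))
      seg_id <- sprintf("seg%02d", s)

      n_base <- rpois(1, cfg$baseline_density * L)
      base_pos <- runif(n_base, 0, L)
      base_lost <- runif(n_base) < rho[a]           # lost in baseline interval
      n_bform <- rpois(1, n_base * rho[a])          # formed in baseline interval
      bform_pos <- runif(n_bform, 0, L)
      turnover_sites <- c(base_pos[base_lost], bform_pos)
      # surviving baseline spines can be lost again during learning
      learn_lost <- !base_lost & runif(n_base) < rho[a]

      n_new <- rpois(1, cfg$new_rate * L)
      # one active hotspot per segment and learning phase: a randomly chosen
      # prior-turnover site near which enriched additions concentrate
      hot_site <- if (length(turnover_sites) > 0) {
        turnover_sites[sample.int(length(turnover_sites), 1)]
      } else NA_real_
      hot <- runif(n_new) < cfg$kappa & !is.na(hot_site)
      new_pos <- runif(n_new, 0, L)
      if (any(hot)) {
        new_pos[hot] <- pmin(pmax(hot_site + runif(sum(hot), -cfg$h, cfg$h), 0), L)
      }
      stable <- runif(n_new) < cfg$p_stable
      appear <- rep(cfg$t_end, n_new)
      if (n_new > 0) {
        appear[stable] <- training_days[sample.int(length(training_days),
                                                   sum(stable), replace = TRUE)]
        early <- training_days[training_days < cfg$t_end]
        if (length(early) > 0 && any(!stable)) {
          appear[!stable] <- early[sample.int(length(early), sum(!stable),
                                              replace = TRUE)]
        } else {
          stable[!stable] <- TRUE               # no pre-terminal session to vanish from
        }
      }

      pos <- c(base_pos, bform_pos, new_pos)
      class <- c(ifelse(base_lost, "baseline_lost",
                        ifelse(learn_lost, "learning_lost", "baseline_stable")),
                 rep("baseline_formed", n_bform),
                 ifelse(stable, "learning_formed_stable",
                        "learning_formed_transient"))
      hotspot <- c(rep(FALSE, n_base + n_bform), hot)
      n <- length(pos)
      if (n == 0L) next
      pres <- matrix(0L, n, nd)
      arow <- function(cls) which(class == cls)
      pres[arow("baseline_lost"), i_pre] <- 1L
      pres[arow("baseline_stable"), seq_len(i_end)] <- 1L
      pres[arow("learning_lost"), seq_len(i0)] <- 1L
      pres[arow("baseline_formed"), i0:i_end] <- 1L
      for (i in arow("learning_formed_stable")) {
        ia <- match(appear[i - n_base - n_bform], days)
        pres[i, ia:i_end] <- 1L
      }
      for (i in arow("learning_formed_transient")) {
        pres[i, match(appear[i - n_base - n_bform], days)] <- 1L
      }
      # baseline-stable spines at follow-up
      bs <- arow("baseline_stable")
      pres[bs, i_fol] <- as.integer(runif(length(bs)) < cfg$p_baseline_follow)
      bf <- arow("baseline_formed")
      pres[bf, i_fol] <- as.integer(runif(length(bf)) < cfg$p_baseline_follow)

      df <- data.frame(animal = a, group = cfg$group, genotype = cfg$genotype,
                       segment = seg_id, segment_length = L,
                       spine_id = sprintf("%s_%s_sp%03d", a, seg_id, seq_len(n)),
                       position = pos, stringsAsFactors = FALSE)
      df[day_col(days)] <- as.data.frame(pres)
      df$true_class <- class
      df$hotspot <- hotspot
      seg_frames[[length(seg_frames) + 1L]] <- df
    }
  }
  spines <- do.call(rbind, seg_frames)
  truth <- spines[, c("animal", "segment", "spine_id", "position",
                      "true_class", "hotspot")]
  names(truth)[names(truth) == "true_class"] <- "class"
  spines$true_class <- NULL; spines$hotspot <- NULL

  map <- spine_map(spines)
  map <- annotate_fates(map, cfg$t_pre, cfg$t0, cfg$t_end)
  cl <- cluster_new_spines(map, d = cfg$cluster_threshold, min_formed = 0)
  new <- cl$spines
  truth$clustered <- FALSE
  truth$survived_followup <- NA
  if (nrow(new) > 0L) {
    p_surv <- ifelse(new$clustered, cfg$surv_clustered, cfg$surv_nonclustered)
    survive <- runif(nrow(new)) < p_surv
    idx <- match(new$spine_id, map$spines$spine_id)
    map$spines[[day_col(cfg$t_follow)]][idx] <- as.integer(survive)
    tidx <- match(new$spine_id, truth$spine_id)
    truth$clustered[tidx] <- new$clustered
    truth$survived_followup[tidx] <- survive
  }
  map$behavior <- generate_behavior(cfg, rho, seed = seed + 1L)
  list(map = map, truth = truth, rho = rho)
}

#' Generate freezing traces coupled to baseline turnover
#'
#' Monotone saturating learning curves whose asymptote increases with the
#' animal's baseline turnover probability rho_i, plus Gaussian noise, so a
#' positive Spearman correlation between turnover and mean freezing is
#' recoverable.
#'
#' @param config a [generator_config()].
#' @param rho named per-animal turnover probabilities.
#' @param seed RNG seed.
#' @return data.frame (`animal`, `day`, `freezing`), days 0 to the learning
#'   end.
#' @export
generate_behavior <- function(config, rho, seed = 1) {
  set.seed(seed)
  cfg <- config
  days <- 0:cfg$t_end
  out <- lapply(names(rho), function(a) {
    base <- max(0, rnorm(1, cfg$freeze_baseline_mean, 2))
    asym <- cfg$freeze_baseline_mean + cfg$freeze_gain * 100 * rho[[a]]
    mu <- base + (asym - base) * (1 - exp(-days / cfg$freeze_tau))
    f <- pmin(pmax(mu + rnorm(length(days), 0, cfg$freeze_noise_sd), 0), 100)
    f[1] <- base                            # pre-shock baseline is noise-free
    data.frame(animal = a, day = days, freezing = f, stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}
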