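#' Summarize a Monte-Carlo null distribution
#'
#' Gaussian fit by moments (mu = mean of the resamples, sigma = their SD) and
#' the add-one empirical p-value p = (1 + #as-extreme) / (R + 1).  One-sided
#' p counts resamples at least as far as the observed value in the direction
#' of (observed - mu) unless `direction` is given; two-sided p counts
#' resamples at least as far from mu in absolute value.
#'
#' @param values R resampled statistic values.
#' @param observed the observed statistic.
#' @param sidedness "one" or "two".
#' @param direction optional "greater"/"less" for one-sided p.
#' @param statistic name of the statistic (label only).
#' @param seed seed used to generate `values` (metadata).
#' @return object of class `null_distribution`.
#' @export
summarize_null <- function(values, observed, sidedness = c("one", "two"),
                           direction = NULL, statistic = "statistic",
                           seed = NA_integer_) {
  sidedness <- match.arg(sidedness)
  R <- length(values)
  if (R < 2L) stop("need at least 2 resamples")
  mu <- mean(values)
  sigma <- sd(values)
  degenerate <- sigma == 0 && observed != mu
  if (sidedness == "one") {
    if (is.null(direction)) {
      direction <- if (observed >= mu) "greater" else "less"
    }
    n_extreme <- if (direction == "greater") sum(values >= observed)
                 else sum(values <= observed)
  } else {
    n_extreme <- sum(abs(values - mu) >= abs(observed - mu))
  }
  p <- (1 + n_extreme) / (R + 1)
  structure(list(statistic = statistic, R = R, values = values,
                 observed = observed, gaussian_mu = mu, gaussian_sigma = sigma,
                 p_empirical = p, sidedness = sidedness, direction = direction,
                 degenerate = degenerate, seed = seed),
            class = "null_distribution")
}

#' @export
print.null_distribution <- function(x, ...) {
  cat(sprintf("<null_distribution> %s | R = %d\n", x$statistic, x$R))
  cat(sprintf("  observed = %.4g | Gaussian fit mu = %.4g, sigma = %.4g\n",
              x$observed, x$gaussian_mu, x$gaussian_sigma))
  cat(sprintf("  empirical p (%s-sided%s) = %.4g%s\n", x$sidedness,
              if (x$sidedness == "one") paste0(", ", x$direction) else "",
              x$p_empirical,
              if (x$degenerate) " [degenerate: zero-variance null]" else ""))
  invisible(x)
}

# --- shared helpers -------------------------------------------------------

# count, per row of a position matrix, how many entries lie within d of
# another entry in the same row (i.e. how many "spines" are clustered)
clustered_counts_matrix <- function(m, d, inclusive = TRUE) {
  R <- nrow(m); k <- ncol(m)
  if (k < 2L) return(rep(0L, R))
  s <- matrix(m[order(row(m), m)], nrow = R, ncol = k, byrow = TRUE)
  gaps <- s[, -1L, drop = FALSE] - s[, -k, drop = FALSE]
  ok <- if (inclusive) gaps <= d else gaps < d
  near <- cbind(ok[, 1L], if (k > 2L) ok[, -1L, drop = FALSE] | ok[, -(k - 1L), drop = FALSE],
                ok[, k - 1L])
  as.integer(rowSums(near))
}

# per-animal segment layout used by the cluster nulls: list of animals, each
# a list(k = new-stable counts per segment, L = lengths,
#        candidates = list of ever-observed positions per segment)
null_layout <- function(map, min_formed = 5) {
  fates_annotated(map)
  cl <- cluster_new_spines(map, min_formed = min_formed)
  incl <- cl$by_animal$animal[cl$by_animal$included]
  if (length(incl) == 0L) stop("no animals eligible (no new stable spines)")
  sp <- map$spines
  new <- cl$spines
  layout <- list()
  for (a in incl) {
    segs <- segment_table(map)
    segs <- segs[segs$animal == a, , drop = FALSE]
    k <- integer(nrow(segs)); cand <- vector("list", nrow(segs))
    for (j in seq_len(nrow(segs))) {
      s <- segs$segment[j]
      k[j] <- sum(new$animal == a & new$segment == s)
      cand[[j]] <- sp$position[sp$animal == a & sp$segment == s]
    }
    layout[[a]] <- list(k = k, L = segs$length, segment = segs$segment,
                        candidates = cand)
  }
  attr(layout, "observed") <- cl$mean_ratio
  layout
}

# --- the four null models -------------------------------------------------

#' Uniform-position null for the clustering percentage
#'
#' For each resample, every segment's new stable spines are replaced by the
#' same number of positions drawn i.i.d. uniformly along that segment; each
#' animal's clustering percentage is computed by pooling counts over its
#' segments, animals are averaged, and the resulting grand mean is one null
#' value.  The observed statistic is the real mean per-animal clustering
#' ratio (same exclusion rule).
#'
#' @param map annotated `spine_map`.
#' @param d cluster threshold (micrometres).
#' @param R number of resamples.
#' @param seed RNG seed (the returned object is a pure function of map,
#'   parameters and seed).
#' @param min_formed animal exclusion threshold.
#' @return a `null_distribution` (values on the ratio scale, 0-1).
#' @export
null_cluster_uniform <- function(map, d = 5, R = 10000, seed = NULL,
                                 min_formed = 5) {
  layout <- null_layout(map, min_formed = min_formed)
  if (!is.null(seed)) set.seed(seed)
  per_animal <- lapply(layout, function(an) {
    use <- an$k > 0L
    if (!any(use)) return(rep(NA_real_, R))
    tot_clustered <- rep(0L, R)
    for (j in which(use)) {
      kj <- an$k[j]
      if (kj == 1L) next                       # no pair possible
      m <- matrix(runif(R * kj, 0, an$L[j]), nrow = R)
      tot_clustered <- tot_clustered + clustered_counts_matrix(m, d)
    }
    tot_clustered / sum(an$k)
  })
  values <- rowMeans(do.call(cbind, per_animal), na.rm = TRUE)
  summarize_null(values, attr(layout, "observed"), sidedness = "one",
                 statistic = "clustering ratio (uniform-position null)",
                 seed = if (is.null(seed)) NA_integer_ else seed)
}

#' Positional-permutation null for the clustering percentage
#'
#' As [null_cluster_uniform()], but resampled positions are drawn without
#' replacement from the segment's ever-observed spine positions (new-spine
#' identity is permuted over candidate sites), so the null respects any
#' process restricting where spines can exist.
#'
#' @inheritParams null_cluster_uniform
#' @return a `null_distribution`.
#' @export
null_cluster_positional <- function(map, d = 5, R = 10000, seed = NULL,
                                    min_formed = 5) {
  layout <- null_layout(map, min_formed = min_formed)
  for (a in names(layout)) {
    an <- layout[[a]]
    short <- an$k > lengths(an$candidates)
    if (any(short)) {
      stop("segment ", an$segment[which(short)[1]], " of animal ", a,
           " has fewer candidate positions than new spines")
    }
  }
  if (!is.null(seed)) set.seed(seed)
  per_animal <- lapply(layout, function(an) {
    use <- an$k > 0L
    if (!any(use)) return(rep(NA_real_, R))
    tot_clustered <- rep(0L, R)
    for (j in which(use)) {
      kj <- an$k[j]
      if (kj == 1L) next
      cand <- an$candidates[[j]]
      m <- t(vapply(seq_len(R), function(i) sample(cand, kj),
                    numeric(kj)))
      tot_clustered <- tot_clustered + clustered_counts_matrix(m, d)
    }
    tot_clustered / sum(an$k)
  })
  values <- rowMeans(do.call(cbind, per_animal), na.rm = TRUE)
  summarize_null(values, attr(layout, "observed"), sidedness = "one",
                 statistic = "clustering ratio (positional-permutation null)",
                 seed = if (is.null(seed)) NA_integer_ else seed)
}

#' Null for the mean distance from clustered spines to turnover sites
#'
#' For each resample the pre-learning turnover spine positions of every
#' contributing segment are randomised (uniform along the segment, or drawn
#' without replacement from the ever-observed positions), the distance from
#' each clustered spine to the nearest randomised turnover position is
#' measured, distances are averaged within animal and then across animals.
#' The observed statistic is the same average on the real turnover positions.
#'
#' @param map annotated `spine_map`.
#' @param variant "uniform" or "positional".
#' @param R number of resamples.
#' @param seed RNG seed.
#' @param d cluster threshold defining clustered spines.
#' @param min_formed animal exclusion threshold for the clustering step.
#' @return a `null_distribution` (micrometres); one-sided "less" by default
#'   (hotspot hypothesis: observed closer than chance).
#' @export
null_nnd_turnover <- function(map, variant = c("uniform", "positional"),
                              R = 10000, seed = NULL, d = 5, min_formed = 5) {
  variant <- match.arg(variant)
  fates_annotated(map)
  cl <- cluster_new_spines(map, d = d, min_formed = min_formed)
  new <- cl$spines[cl$spines$clustered, , drop = FALSE]
  if (nrow(new) == 0L) stop("no clustered spines")
  sp <- map$spines
  seg_key  <- paste(sp$animal, sp$segment, sep = "\r")
  new_key  <- paste(new$animal, new$segment, sep = "\r")
  segs <- segment_table(map)
  segs_key <- paste(segs$animal, segs$segment, sep = "\r")

  # contributing segments: >=1 clustered spine and >=1 turnover spine
  contrib <- intersect(unique(new_key), unique(seg_key[sp$baseline_turnover]))
  if (length(contrib) == 0L) stop("no segment has both clustered and turnover spines")

  if (!is.null(seed)) set.seed(seed)
  obs_d  <- list(); null_d <- list(); seg_animal <- character(0)
  for (k in contrib) {
    cpos <- new$position[new_key == k]
    tpos <- sp$position[seg_key == k & sp$baseline_turnover]
    L <- segs$length[segs_key == k]
    m <- length(tpos)
    draw <- if (variant == "uniform") {
      matrix(runif(R * m, 0, L), nrow = R)
    } else {
      cand <- sp$position[seg_key == k]
      if (m > length(cand)) stop("segment ", k, ": not enough candidate positions")
      t(vapply(seq_len(R), function(i) sample(cand, m), numeric(m)))
    }
    obs_k  <- vapply(cpos, function(p) min(abs(p - tpos)), numeric(1))
    null_k <- vapply(cpos, function(p) {
      matrixMin <- abs(draw - p)
      if (m == 1L) as.vector(matrixMin) else do.call(pmin, as.data.frame(matrixMin))
    }, numeric(R))
    obs_d[[k]]  <- obs_k
    null_d[[k]] <- if (is.matrix(null_k)) null_k else matrix(null_k, nrow = R)
    seg_animal <- c(seg_animal, new$animal[new_key == k][1])
  }
  animals <- unique(seg_animal)
  obs_per_animal  <- vapply(animals, function(a)
    mean(unlist(obs_d[seg_animal == a])), numeric(1))
  null_per_animal <- vapply(animals, function(a)
    rowMeans(do.call(cbind, null_d[seg_animal == a])), numeric(R))
  if (is.null(dim(null_per_animal))) null_per_animal <- matrix(null_per_animal, nrow = R)
  values <- rowMeans(null_per_animal)
  summarize_null(values, mean(obs_per_animal), sidedness = "one",
                 direction = "less",
                 statistic = paste0("mean clustered-to-turnover NND (",
                                    variant, " null)"),
                 seed = if (is.null(seed)) NA_integer_ else seed)
}

#' Concordance null: permuting clustered-spine counts across segments
#'
#' Each segment is categorised by its pre-learning turnover and
#' learning-related clustering counts: both > 0 ("both"), both zero
#' ("neither"), turnover only, or clusters only.  The null permutes the
#' vector of clustered-spine counts across each animal's segments (turnover
#' counts fixed), recomputes the four category percentages, and averages
#' animals with equal weight.  Animals with fewer than two segments are
#' skipped with a warning.
#'
#' @param map annotated `spine_map`.
#' @param R number of permutation resamples.
#' @param seed RNG seed.
#' @param d cluster threshold.
#' @return named list of four `null_distribution`s: `both`, `neither`,
#'   `turnover_only`, `cluster_only` (percentage-of-segments scale, 0-100).
#' @export
null_concordance <- function(map, R = 10000, seed = NULL, d = 5) {
  dens <- segment_densities(map, d = d)
  keep <- ave(seq_len(nrow(dens)), dens$animal, FUN = length) >= 2
  if (any(!keep)) {
    warning("skipping animal(s) with < 2 segments: ",
            paste(unique(dens$animal[!keep]), collapse = ", "))
    dens <- dens[keep, , drop = FALSE]
  }
  if (nrow(dens) == 0L) stop("no animal has >= 2 segments")
  categories <- function(turn, clus) {
    c(both = mean(turn > 0 & clus > 0), neither = mean(turn == 0 & clus == 0),
      turnover_only = mean(turn > 0 & clus == 0),
      cluster_only = mean(turn == 0 & clus > 0)) * 100
  }
  by_animal <- split(dens, dens$animal)
  observed <- rowMeans(vapply(by_animal, function(s)
    categories(s$n_turnover, s$n_clustered), numeric(4)))
  if (!is.null(seed)) set.seed(seed)
  values <- matrix(NA_real_, nrow = R, ncol = 4,
                   dimnames = list(NULL, names(observed)))
  for (r in seq_len(R)) {
    values[r, ] <- rowMeans(vapply(by_animal, function(s)
      categories(s$n_turnover, sample(s$n_clustered)), numeric(4)))
  }
  out <- lapply(colnames(values), function(cat)
    summarize_null(values[, cat], observed[cat], sidedness = "one",
                   statistic = paste0("segment concordance: % ", cat),
                   seed = if (is.null(seed)) NA_integer_ else seed))
  names(out) <- colnames(values)
  out
}
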