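#' Spine turnover ratio between two imaging sessions
#'
#' Turnover ratio = (formed + lost) / (n_a + n_b), where formed/lost are the
#' spines appearing/disappearing between sessions `day_a` and `day_b` and
#' n_a, n_b are the spine counts at the two sessions.  Counts are pooled over
#' all of an animal's segments before dividing.
#'
#' @param map a `spine_map`.
#' @param day_a,day_b session day labels (day_a < day_b).
#' @return data.frame with one row per animal: `n_formed`, `n_lost`, `n_t1`,
#'   `n_t2`, `ratio`.  Animals with no spines at either session are dropped
#'   with a warning.
#' @export
turnover_ratio <- function(map, day_a, day_b) {
  stopifnot(inherits(map, "spine_map"))
  pa <- presence_at(map, day_a)
  pb <- presence_at(map, day_b)
  an <- map$spines$animal
  agg <- function(x) tapply(x, an, sum)
  out <- data.frame(
    animal   = sort(unique(an)),
    n_formed = as.vector(agg(pa == 0 & pb == 1)),
    n_lost   = as.vector(agg(pa == 1 & pb == 0)),
    n_t1     = as.vector(agg(pa == 1)),
    n_t2     = as.vector(agg(pb == 1)),
    stringsAsFactors = FALSE
  )
  denom <- out$n_t1 + out$n_t2
  if (all(denom == 0)) stop("turnover ratio undefined: no spines at either session")
  if (any(denom == 0)) {
    warning("dropping animal(s) with no spines at either session: ",
            paste(out$animal[denom == 0], collapse = ", "))
    out <- out[denom > 0, , drop = FALSE]
  }
  out$ratio <- (out$n_formed + out$n_lost) / (out$n_t1 + out$n_t2)
  out
}

#' Connected-component clustering of 1-D positions
#'
#' Two positions are adjacent when they lie within `d` of each other;
#' clusters are the connected components of that adjacency graph (chaining
#' allowed), and only components of size >= 2 count as clusters.
#'
#' @param pos numeric positions (micrometres along one segment).
#' @param d distance threshold; comparison is inclusive (<= d) by default.
#' @param inclusive use `<= d` (default) rather than `< d`.
#' @return integer vector, same length as `pos`: cluster id (1, 2, ...) or
#'   0 for singletons.
#' @export
cluster_positions <- function(pos, d = 5, inclusive = TRUE) {
  n <- length(pos)
  if (n == 0L) return(integer(0))
  o <- order(pos)
  gap_ok <- if (inclusive) diff(pos[o]) <= d else diff(pos[o]) < d
  comp <- cumsum(c(1L, !gap_ok))        # component id in sorted order
  size <- tabulate(comp)
  ids <- integer(n)
  keep <- size[comp] >= 2L
  ids[o] <- ifelse(keep, match(comp, unique(comp[keep])), 0L)
  ids[is.na(ids)] <- 0L
  ids
}

#' Cluster newly formed stable spines and compute per-animal clustering ratios
#'
#' Clustered spines are new stable spines (formed after day 0, present at the
#' end of learning) lying within `d` micrometres of another new stable spine
#' on the same segment; groups are transitive.  The clustering ratio is
#' (# clustered spines) / (# new stable spines), pooled over an animal's
#' segments.  Animals with fewer than `min_formed` spines formed during
#' learning are excluded from the ratio table (standard exclusion rule).
#'
#' @param map an annotated `spine_map` (see [annotate_fates()]).
#' @param d distance threshold in micrometres (default 5).
#' @param min_formed exclusion threshold on spines formed during learning.
#' @param inclusive inclusive (`<= d`) comparison, see [cluster_positions()].
#' @return list with `spines` (the new-stable subset with `cluster` id and
#'   `clustered` flag), `by_animal` (data.frame: `n_new_stable`,
#'   `n_clustered`, `n_formed`, `clustering_ratio`, `included`) and
#'   `mean_ratio` (mean per-animal ratio over included animals).
#' @export
cluster_new_spines <- function(map, d = 5, min_formed = 5, inclusive = TRUE) {
  stopifnot(inherits(map, "spine_map"))
  fates_annotated(map)
  sp <- map$spines
  new <- sp[sp$new_stable, , drop = FALSE]
  if (nrow(new) > 0L) {
    seg_key <- paste(new$animal, new$segment, sep = "\r")
    cl <- integer(nrow(new))
    for (k in unique(seg_key)) {
      i <- seg_key == k
      cl[i] <- cluster_positions(new$position[i], d = d, inclusive = inclusive)
    }
    new$cluster <- cl
    new$clustered <- cl > 0L
  } else {
    new$cluster <- integer(0)
    new$clustered <- logical(0)
  }
  animals <- sort(unique(sp$animal))
  tab <- function(x, flag) {
    v <- tapply(flag, x, sum)
    out <- setNames(rep(0L, length(animals)), animals)
    out[names(v)] <- as.integer(v)
    out
  }
  by_animal <- data.frame(
    animal       = animals,
    n_new_stable = as.vector(tab(sp$animal[sp$new_stable], rep(TRUE, sum(sp$new_stable)))),
    n_clustered  = as.vector(tab(new$animal, new$clustered)),
    n_formed     = as.vector(tab(sp$animal[sp$learning_formed],
                                 rep(TRUE, sum(sp$learning_formed)))),
    stringsAsFactors = FALSE
  )
  by_animal$clustering_ratio <- ifelse(by_animal$n_new_stable > 0,
                                       by_animal$n_clustered / by_animal$n_new_stable,
                                       NA_real_)
  by_animal$included <- by_animal$n_formed >= min_formed &
    !is.na(by_animal$clustering_ratio)
  mean_ratio <- if (any(by_animal$included)) {
    mean(by_animal$clustering_ratio[by_animal$included])
  } else NA_real_
  list(spines = new, by_animal = by_animal, mean_ratio = mean_ratio,
       d = d, min_formed = min_formed)
}

#' Nearest-neighbour distances between two sets of 1-D positions
#'
#' For each source position, the distance to the closest target position on
#' the same coordinate axis.  When source and target are the same set, each
#' spine is excluded from its own neighbour search.
#'
#' @param source,target numeric position vectors (same segment).
#' @param self TRUE when `target` is the same physical set as `source`
#'   (matched by index), so self-distances are excluded.
#' @return numeric vector of distances, one per source position that has at
#'   least one eligible target (others are skipped).
#' @export
nnd_1d <- function(source, target, self = FALSE) {
  if (length(source) == 0L) return(numeric(0))
  out <- numeric(0)
  for (i in seq_along(source)) {
    tgt <- if (self) target[-i] else target
    if (length(tgt) == 0L) next
    out <- c(out, min(abs(source[i] - tgt)))
  }
  out
}

# apply nnd_1d per segment across a map; source_flag / target_flag are
# logical columns of map$spines
nnd_by_segment <- function(map, source_flag, target_flag) {
  sp <- map$spines
  seg_key <- paste(sp$animal, sp$segment, sep = "\r")
  src <- sp[[source_flag]]
  tgt <- sp[[target_flag]]
  self <- identical(source_flag, target_flag)
  res <- data.frame(animal = character(0), distance = numeric(0),
                    stringsAsFactors = FALSE)
  for (k in unique(seg_key[src])) {
    i <- seg_key == k
    dists <- nnd_1d(sp$position[i & src], sp$position[i & tgt], self = self)
    if (length(dists) > 0L) {
      res <- rbind(res, data.frame(animal = sp$animal[i & src][1],
                                   distance = dists, stringsAsFactors = FALSE))
    }
  }
  res
}

#' Nearest-neighbour distances between gained spines
#'
#' Distance from each learning-formed new stable spine to its closest new
#' stable neighbour on the same segment.
#'
#' @param map annotated `spine_map`.
#' @return data.frame (`animal`, `distance`).
#' @export
nnd_new_spines <- function(map) {
  fates_annotated(map)
  nnd_by_segment(map, "new_stable", "new_stable")
}

#' Nearest-neighbour distance from each lost spine to the closest gained spine
#'
#' @param map annotated `spine_map`.
#' @param d cluster threshold used to label the gained neighbour as clustered.
#' @return data.frame (`animal`, `distance`, `neighbor_clustered`).
#' @export
nnd_lost_to_gained <- function(map, d = 5) {
  fates_annotated(map)
  cl <- cluster_new_spines(map, d = d, min_formed = 0)
  sp <- map$spines
  seg_key <- paste(sp$animal, sp$segment, sep = "\r")
  new <- cl$spines
  new_key <- paste(new$animal, new$segment, sep = "\r")
  res <- data.frame(animal = character(0), distance = numeric(0),
                    neighbor_clustered = logical(0), stringsAsFactors = FALSE)
  for (k in unique(seg_key[sp$learning_lost])) {
    lost_pos <- sp$position[seg_key == k & sp$learning_lost]
    j <- new_key == k
    if (sum(j) == 0L) next
    for (p in lost_pos) {
      dist_all <- abs(p - new$position[j])
      nearest <- which.min(dist_all)
      res <- rbind(res, data.frame(animal = new$animal[j][1],
                                   distance = dist_all[nearest],
                                   neighbor_clustered = new$clustered[j][nearest],
                                   stringsAsFactors = FALSE))
    }
  }
  res
}

#' Two-sample Kolmogorov-Smirnov test
#'
#' D = sup |ECDF_x - ECDF_y| with the asymptotic two-sided p-value.
#'
#' @param x,y numeric samples (non-empty).
#' @return list with `D` and `p`.
#' @export
ks_two_sample <- function(x, y) {
  if (length(x) == 0L || length(y) == 0L) stop("both samples must be non-empty")
  kt <- suppressWarnings(ks.test(x, y, exact = FALSE))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}

#' Survival of clustered vs non-clustered training-added spines
#'
#' The cohort is the new stable spines (formed during training, present at
#' the end of learning), partitioned into clustered and non-clustered by
#' [cluster_new_spines()].  Survival is the fraction of each sub-cohort
#' still present at the follow-up session, per animal.
#'
#' @param map annotated `spine_map`.
#' @param t_follow follow-up day label (after the learning end).
#' @param d cluster threshold (micrometres).
#' @param min_formed animal exclusion threshold (see [cluster_new_spines()]).
#' @return data.frame per animal: `n_clustered`, `n_nonclustered`,
#'   `survival_clustered`, `survival_nonclustered` (NA when the sub-cohort is
#'   empty).
#' @export
survival_rate <- function(map, t_follow, d = 5, min_formed = 5) {
  fates_annotated(map)
  cl <- cluster_new_spines(map, d = d, min_formed = min_formed)
  new <- cl$spines
  if (nrow(new) == 0L) stop("no new stable spines; survival undefined")
  alive <- presence_at(map, t_follow)[match(
    paste(new$animal, new$segment, new$spine_id),
    paste(map$spines$animal, map$spines$segment, map$spines$spine_id))] == 1
  out <- lapply(split(seq_len(nrow(new)), new$animal), function(i) {
    clu <- new$clustered[i]
    data.frame(
      n_clustered = sum(clu), n_nonclustered = sum(!clu),
      survival_clustered = if (any(clu)) mean(alive[i][clu]) else NA_real_,
      survival_nonclustered = if (any(!clu)) mean(alive[i][!clu]) else NA_real_)
  })
  res <- do.call(rbind, out)
  res$animal <- names(out)
  rownames(res) <- NULL
  res[, c("animal", "n_clustered", "n_nonclustered",
          "survival_clustered", "survival_nonclustered")]
}

#' Per-segment turnover and clustering densities
#'
#' Counts of baseline-interval turnover spines and of learning-related
#' clustered spines, each normalised by segment length so segments of
#' different lengths are comparable.
#'
#' @param map annotated `spine_map`.
#' @param d cluster threshold (micrometres).
#' @return data.frame per segment: `length`, `n_turnover`, `n_clustered`,
#'   `turnover_density`, `cluster_density` (per micrometre).
#' @export
segment_densities <- function(map, d = 5) {
  fates_annotated(map)
  segs <- segment_table(map)
  if (any(segs$length <= 0)) stop("segment length must be > 0")
  cl <- cluster_new_spines(map, d = d, min_formed = 0)
  sp <- map$spines
  key <- function(a, s) paste(a, s, sep = "\r")
  seg_key <- key(segs$animal, segs$segment)
  turn <- table(key(sp$animal, sp$segment)[sp$baseline_turnover])
  clus <- table(key(cl$spines$animal, cl$spines$segment)[cl$spines$clustered])
  segs$n_turnover  <- as.integer(ifelse(is.na(turn[seg_key]), 0, turn[seg_key]))
  segs$n_clustered <- as.integer(ifelse(is.na(clus[seg_key]), 0, clus[seg_key]))
  segs$turnover_density <- segs$n_turnover / segs$length
  segs$cluster_density  <- segs$n_clustered / segs$length
  segs
}

#' Learning rate from a freezing trace
#'
#' Slope of the line connecting baseline freezing (first day of the trace,
#' before the first shock) and the asymptote level, where the asymptote is
#' the highest freezing that occurs chronologically before any decrease:
#' m = (asymptote - baseline) / (day of asymptote - baseline day).
#'
#' @param day integer day labels (ascending; first entry is the baseline day).
#' @param freezing percent freezing per day.
#' @return slope in percent freezing per day.
#' @export
learning_rate <- function(day, freezing) {
  stopifnot(length(day) == length(freezing))
  if (length(day) < 2L) stop("trace needs a baseline and at least one training day")
  o <- order(day)
  day <- day[o]; freezing <- freezing[o]
  drops <- which(diff(freezing) < 0)
  i_asym <- if (length(drops) == 0L) length(freezing) else drops[1]
  if (i_asym == 1L) return(0)           # immediate decrease: flat-or-falling trace
  m <- (freezing[i_asym] - freezing[1]) / (day[i_asym] - day[1])
  m
}

#' Activity suppression ratio
#'
#' test / (baseline + test): 0 means complete suppression during the test,
#' 0.5 means activity unchanged.
#'
#' @param test,baseline nonnegative activity measures (vectorised).
#' @return ratio in \[0, 1\].
#' @export
suppression_ratio <- function(test, baseline) {
  if (any(test < 0 | baseline < 0)) stop("activities must be nonnegative")
  if (any(test + baseline == 0)) stop("suppression ratio undefined: both activities zero")
  test / (baseline + test)
}
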