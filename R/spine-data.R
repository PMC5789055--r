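#' @useDynLib spineclust, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats aov lm runif rnorm rpois rbinom sd quantile ks.test
#'   pf coef anova setNames cor ave
#' @importFrom utils read.csv write.csv combn packageVersion
NULL

# day labels <-> presence column names ("d-3", "d0", "d5", ...)
day_col <- function(day) paste0("d", day)

col_day <- function(col) as.integer(sub("^d", "", col))

is_day_col <- function(nm) grepl("^d-?[0-9]+$", nm)

#' Construct a spine map
#'
#' A spine map is the container for longitudinal spine-imaging data: one row
#' per spine, with its animal, dendritic segment, 1-D position along the
#' segment (micrometres, base-to-base path convention) and a 0/1 presence
#' record per imaging session.  Sessions are labelled by integer days
#' relative to the first training day (negative days are baseline sessions).
#'
#' @param spines data.frame with columns `animal`, `group`, `genotype`,
#'   `segment`, `segment_length`, `spine_id`, `position`, and one 0/1 column
#'   per session named `d<day>` (e.g. `d-3`, `d0`, `d5`).
#' @param behavior optional data.frame with columns `animal`, `day`,
#'   `freezing` (percent, 0-100).
#' @return An object of class `spine_map`: a list with elements `spines`,
#'   `schedule` (sorted integer day labels) and `behavior`.
#' @export
spine_map <- function(spines, behavior = NULL) {
  stopifnot(is.data.frame(spines))
  required <- c("animal", "group", "genotype", "segment", "segment_length",
                "spine_id", "position")
  missing_cols <- setdiff(required, names(spines))
  if (length(missing_cols) > 0L) {
    stop("spine table is missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  day_cols <- names(spines)[is_day_col(names(spines))]
  if (length(day_cols) < 2L) {
    stop("spine table needs at least two session columns (named d<day>)")
  }
  schedule <- sort(col_day(day_cols))
  # reorder presence columns chronologically
  spines <- spines[, c(required, day_col(schedule)), drop = FALSE]
  spines$animal  <- as.character(spines$animal)
  spines$segment <- as.character(spines$segment)
  spines$spine_id <- as.character(spines$spine_id)

  bad <- which(spines$position < 0 | spines$position > spines$segment_length)
  if (length(bad) > 0L) {
    stop(sprintf("spine position outside [0, segment_length] at row(s): %s",
                 paste(bad, collapse = ", ")))
  }
  if (any(spines$segment_length <= 0)) stop("segment_length must be > 0")
  key <- paste(spines$animal, spines$segment, spines$spine_id)
  if (anyDuplicated(key)) {
    stop("duplicate spine_id within a segment: ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  }
  pres <- as.matrix(spines[, day_col(schedule), drop = FALSE])
  if (!all(pres %in% c(0, 1, NA))) stop("presence columns must be 0/1 (or NA)")
  all_absent <- rowSums(pres == 1, na.rm = TRUE) == 0
  if (any(all_absent)) {
    stop("spine(s) never present in any session at row(s): ",
         paste(which(all_absent), collapse = ", "))
  }
  structure(list(spines = spines, schedule = schedule, behavior = behavior),
            class = "spine_map")
}

#' @export
print.spine_map <- function(x, ...) {
  cat(sprintf("<spine_map> %d spines | %d segments | %d animals | sessions: %s\n",
              nrow(x$spines),
              length(unique(paste(x$spines$animal, x$spines$segment))),
              length(unique(x$spines$animal)),
              paste(x$schedule, collapse = ", ")))
  invisible(x)
}

#' Read a spine table from delimited text
#'
#' @param path CSV (or TSV, by file extension) file with the columns listed
#'   in [spine_map()].
#' @param behavior_path optional behaviour CSV (`animal`, `day`, `freezing`).
#' @return A `spine_map`.
#' @export
read_spine_table <- function(path, behavior_path = NULL) {
  if (!file.exists(path)) stop("spine table not found: ", path)
  sep <- if (grepl("\\.tsv$", path, ignore.case = TRUE)) "\t" else ","
  spines <- read.csv(path, sep = sep, check.names = FALSE,
                     stringsAsFactors = FALSE)
  behavior <- NULL
  if (!is.null(behavior_path)) {
    if (!file.exists(behavior_path)) stop("behavior table not found: ", behavior_path)
    behavior <- read.csv(behavior_path, stringsAsFactors = FALSE)
  }
  spine_map(spines, behavior = behavior)
}

#' Write a spine map back to delimited text
#'
#' @param map a `spine_map`.
#' @param path output CSV path.
#' @export
write_spine_table <- function(map, path) {
  stopifnot(inherits(map, "spine_map"))
  write.csv(map$spines, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

presence_at <- function(map, day) {
  if (!day %in% map$schedule) stop("day ", day, " is not in the imaging schedule")
  map$spines[[day_col(day)]]
}

#' Annotate per-spine fates over the baseline / learning / follow-up windows
#'
#' Classifies every spine relative to three named sessions: the last two
#' baseline sessions (`t_pre`, `t0`) and the end of learning (`t_end`).
#' A spine that disappears and reappears is scored as two events (presence is
#' per session; identity is not persisted across gaps).
#'
#' Added columns:
#' \describe{
#'   \item{baseline_stable}{present at both `t_pre` and `t0`}
#'   \item{baseline_formed}{absent at `t_pre`, present at `t0`}
#'   \item{baseline_lost}{present at `t_pre`, absent at `t0`}
#'   \item{baseline_turnover}{formed or lost in the baseline interval; these
#'     positions are the "turnover sites" of the hotspot analyses}
#'   \item{learning_formed}{absent at `t0`, present at some session in
#'     (`t0`, `t_end`]}
#'   \item{learning_lost}{present at `t0`, absent at `t_end`}
#'   \item{new_stable}{absent at `t0` and present at `t_end` (newly formed
#'     and stably retained; the population entering the clustering ratio)}
#' }
#'
#' @param map a `spine_map`.
#' @param t_pre,t0,t_end day labels present in the schedule; `t0` is the
#'   learning start (day 0), `t_end` the learning end.
#' @return The map with fate columns added to `$spines` and the window
#'   recorded in `attr(map, "fate_days")`.
#' @export
annotate_fates <- function(map, t_pre, t0, t_end) {
  stopifnot(inherits(map, "spine_map"))
  for (d in c(t_pre, t0, t_end)) {
    if (!d %in% map$schedule) stop("day ", d, " is not in the imaging schedule")
  }
  if (!(t_pre < t0 && t0 < t_end)) stop("need t_pre < t0 < t_end")
  pre  <- presence_at(map, t_pre)
  p0   <- presence_at(map, t0)
  pend <- presence_at(map, t_end)
  between <- map$schedule[map$schedule > t0 & map$schedule <= t_end]
  pres_between <- as.matrix(map$spines[, day_col(between), drop = FALSE])
  seen_after <- rowSums(pres_between == 1, na.rm = TRUE) > 0

  sp <- map$spines
  sp$baseline_stable   <- pre == 1 & p0 == 1
  sp$baseline_formed   <- pre == 0 & p0 == 1
  sp$baseline_lost     <- pre == 1 & p0 == 0
  sp$baseline_turnover <- sp$baseline_formed | sp$baseline_lost
  sp$learning_formed   <- p0 == 0 & seen_after
  sp$learning_lost     <- p0 == 1 & pend == 0
  sp$new_stable        <- p0 == 0 & pend == 1
  map$spines <- sp
  attr(map, "fate_days") <- c(t_pre = t_pre, t0 = t0, t_end = t_end)
  map
}

fates_annotated <- function(map) {
  if (!"new_stable" %in% names(map$spines)) {
    stop("spine fates not annotated; call annotate_fates() first")
  }
  invisible(TRUE)
}

# per-segment bookkeeping table: one row per (animal, segment)
segment_table <- function(map) {
  sp <- map$spines
  key <- paste(sp$animal, sp$segment, sep = "\r")
  idx <- !duplicated(key)
  data.frame(animal = sp$animal[idx], segment = sp$segment[idx],
             length = sp$segment_length[idx], stringsAsFactors = FALSE)
}
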