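# build a spine_map from a compact table: one row per spine with columns
# animal, segment, length, position, presence (string of 0/1 per session)
build_map <- function(df, days = c(-3, 0, 2, 5, 35), group = "trained",
                      genotype = "WT", behavior = NULL) {
  pres <- t(vapply(strsplit(df$presence, ""),
                   function(s) as.integer(s), integer(length(days))))
  spines <- data.frame(animal = df$animal, group = group, genotype = genotype,
                       segment = df$segment, segment_length = df$length,
                       spine_id = sprintf("sp%03d", seq_len(nrow(df))),
                       position = df$position,
                       stringsAsFactors = FALSE, check.names = FALSE)
  spines[paste0("d", days)] <- as.data.frame(pres)
  spine_map(spines, behavior = behavior)
}

# shorthand single-animal/segment map from positions + presence strings
seg_map <- function(position, presence, length = 50, animal = "a1",
                    segment = "s1", ...) {
  build_map(data.frame(animal = animal, segment = segment, length = length,
                       position = position, presence = presence,
                       stringsAsFactors = FALSE), ...)
}

annotated <- function(map, t_pre = -3, t0 = 0, t_end = 5) {
  annotate_fates(map, t_pre, t0, t_end)
}

# minimal hand-built network for engram metric unit tests
toy_net <- function(subunit, pos, w, birth = 0L, neuron = 1L) {
  n <- length(pos)
  syn <- data.frame(neuron = rep_len(neuron, n), subunit = rep_len(subunit, n),
                    pos = pos, w = rep_len(w, n),
                    input = seq_len(n), tag = 0L, prp = 0,
                    birth = rep_len(as.integer(birth), n))
  structure(list(params = model_params(), syn = syn,
                 subunit_rate = rep(0.1, 20), n_high_turnover = 0, day = 0L),
            class = "stc_network")
}

# presence strings used throughout:
#   days      -3 0 2 5 35
#   "11110" = baseline-stable through learning, absent at follow-up
#   "00110" = formed in training, stable at day 5 (new stable)
#   "10000" = lost in the baseline interval (turnover site)
#   "01110" = formed in the baseline interval (turnover site)
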