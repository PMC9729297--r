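# Shared fixtures and independent oracles used across the suite.

# Construct a pairwise dataset directly from an intensity matrix, for
# tests that exercise statistics without running the whole pipeline.
make_pairwise <- function(values, strain_a = "A", strain_b = "B",
                          stage = "normalized") {
  nf <- nrow(values); ns <- ncol(values)
  stopifnot(ns %% 2 == 0)
  half <- ns / 2
  samples <- data.frame(
    sample_id = paste0(rep(c(strain_a, strain_b), each = half), "_",
                       rep(seq_len(half), 2)),
    strain = rep(c(strain_a, strain_b), each = half),
    replicate_index = rep(seq_len(half), 2),
    stringsAsFactors = FALSE
  )
  colnames(values) <- samples$sample_id
  features <- data.frame(
    feature_id = sprintf("F%04d", seq_len(nf)),
    polarity = "positive",
    mz = 200 + seq_len(nf), rt = 100 + seq_len(nf),
    stringsAsFactors = FALSE
  )
  rownames(values) <- features$feature_id
  structure(list(strain_a = strain_a, strain_b = strain_b,
                 features = features, samples = samples,
                 values = values, raw_values = values,
                 stage = stage, total_missing_done = TRUE,
                 exclusives = NULL),
            class = "pairwise_dataset")
}

# Build a tiny feature matrix from a presence/intensity grid.
make_matrix <- function(values, strains, reps_per_strain) {
  samples <- data.frame(
    sample_id = unlist(lapply(strains, function(s)
      paste0(s, "_", seq_len(reps_per_strain)))),
    strain = rep(strains, each = reps_per_strain),
    replicate_index = rep(seq_len(reps_per_strain), length(strains)),
    stringsAsFactors = FALSE
  )
  stopifnot(ncol(values) == nrow(samples))
  colnames(values) <- samples$sample_id
  features <- data.frame(
    feature_id = sprintf("F%04d", seq_len(nrow(values))),
    polarity = "positive",
    mz = 200 + seq_len(nrow(values)),
    rt = 100 + 10 * seq_len(nrow(values)),
    stringsAsFactors = FALSE
  )
  rownames(values) <- features$feature_id
  structure(list(features = features, samples = samples,
                 values = values),
            class = "feature_matrix")
}

# Brute-force alignment oracle: all-pairs connected components under
# the same m/z (ppm, relative to the pair mean) and RT gates.
brute_force_groups <- function(obs, ppm_tol, rt_tol) {
  n <- nrow(obs)
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      ppm <- abs(obs$mz[i] - obs$mz[j]) /
        ((obs$mz[i] + obs$mz[j]) / 2) * 1e6
      if (ppm <= ppm_tol && abs(obs$rt[i] - obs$rt[j]) <= rt_tol) {
        ri <- find(i); rj <- find(j)
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  vapply(seq_len(n), find, integer(1))
}

# Canonical signature of a partition of observations: sorted group
# member keys, sorted.
partition_signature <- function(keys, groups) {
  sig <- vapply(split(keys, groups),
                function(k) paste(sort(k), collapse = "|"),
                character(1))
  sort(unname(sig))
}

# Exhaustive-enumeration oracle for the two missingness filters: given
# per-strain presence counts, return which features survive.
enumerate_filters <- function(pres_a, n_a, pres_b, n_b, threshold) {
  kept_total <- pres_a > 0 & pres_b > 0
  kept_presence <- kept_total &
    (pres_a >= ceiling(threshold * n_a) |
       pres_b >= ceiling(threshold * n_b))
  list(exclusive = !kept_total, kept = kept_presence)
}

# Required adduct of a subclass in a polarity (lookup over the
# exported rule table).
rule_adduct_for_test <- function(subclass, polarity) {
  rules <- adduct_rules()
  idx <- match(subclass, rules$subclass)
  ifelse(polarity == "positive", rules$positive_adduct[idx],
         rules$negative_adduct[idx])
}

# A small noiseless simulation shared by annotation/alignment tests.
noiseless_sim_config <- function(n_lipids = 40, seed = 11,
                                 strains = c("OP50", "HA-114", "R0011")) {
  sim_config(strains = strains, n_lipids = n_lipids,
             noise_cv = 0, ppm_noise_sd = 0, rt_jitter_sd = 0,
             dropout_prob = 0, unknown_feature_rate = 0.2,
             n_planted = 0, spike_standards = FALSE, seed = seed)
}
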