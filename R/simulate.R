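# Ground-truthed synthetic LC-MS feature generator.
#
# Emulates the study design: three bacterial strains, six replicates
# each, dual-polarity acquisition, class-specific adduct ions, ~5 ppm
# mass accuracy, retention-time jitter, log-normal intensities with
# planted fold changes, and feature dropout. Every simulated peak is
# traceable to a ground-truth lipid so downstream stages can be scored
# for recovery.

.default_class_proportions <- function(strains) {
  props <- list(
    "OP50"   = c(FFA = 0.25, PE = 0.45, PG = 0.15, PC = 0.10,
                 MGDG = 0.00, DGDG = 0.00, LPG = 0.05),
    "HA-114" = c(FFA = 0.30, PE = 0.15, PG = 0.15, PC = 0.10,
                 MGDG = 0.12, DGDG = 0.08, LPG = 0.10),
    "R0011"  = c(FFA = 0.25, PE = 0.15, PG = 0.15, PC = 0.12,
                 MGDG = 0.13, DGDG = 0.10, LPG = 0.10)
  )
  out <- props[strains]
  # unseen strain labels fall back to the HA-114-like profile
  for (i in which(vapply(out, is.null, logical(1)))) {
    out[[i]] <- props[["HA-114"]]
  }
  names(out) <- strains
  out
}

#' Simulation configuration
#'
#' Defaults emulate the study conditions: strains OP50, HA-114 and
#' R0011 with six replicates each, dual-polarity acquisition, a 5 ppm
#' instrument (mass-error scale 1 ppm, truncated at 5), 3 s
#' retention-time jitter over a ~80 min gradient, a 20% coefficient of
#' variation on intensities, 5% random dropout, and per-strain
#' lipid-class mixes in which the OP50-like strain carries no
#' MGDG/DGDG and is PE-rich.
#'
#' @param strains Strain labels.
#' @param replicates Replicates per strain (>= 2).
#' @param n_lipids Number of ground-truth library lipids.
#' @param class_proportions Named list (per strain) of named subclass
#'   proportion vectors, each summing to 1.
#' @param noise_cv Coefficient of variation of intensities; the log2
#'   intensity s.d. is `log2(1 + noise_cv)`.
#' @param ppm_noise_sd Mass-error scale in ppm (errors truncated at
#'   +/- 5 ppm).
#' @param rt_jitter_sd Retention-time jitter s.d. (seconds).
#' @param unknown_feature_rate Unknown features (no library
#'   counterpart, by construction > 10 ppm from every library adduct
#'   m/z) added per library lipid.
#' @param dropout_prob Per-observation dropout probability; scalar or
#'   named per-strain vector.
#' @param left_censor If `TRUE`, dropout probability quadruples for
#'   intensities in the lowest quartile (left-censored missingness).
#' @param n_planted Number of lipids with a planted between-strain
#'   effect.
#' @param planted_log2fc Planted effect size (log2 fold change).
#' @param rt_range Gradient window (seconds) for true retention times.
#' @param base_log2_range Range of baseline log2 intensities.
#' @param spike_standards Spike the six internal standards into every
#'   sample.
#' @param seed Master seed; stage-level child seeds are derived from it
#'   deterministically.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(strains = c("OP50", "HA-114", "R0011"),
                       replicates = 6,
                       n_lipids = 150,
                       class_proportions = NULL,
                       noise_cv = 0.2,
                       ppm_noise_sd = 1,
                       rt_jitter_sd = 3,
                       unknown_feature_rate = 0.2,
                       dropout_prob = 0.05,
                       left_censor = FALSE,
                       n_planted = 30,
                       planted_log2fc = log2(3),
                       rt_range = c(60, 4800),
                       base_log2_range = c(14, 22),
                       spike_standards = TRUE,
                       seed = 1L) {
  if (is.null(class_proportions)) {
    class_proportions <- .default_class_proportions(strains)
  }
  stopifnot(length(strains) >= 1, replicates >= 2, n_lipids >= 1,
            noise_cv >= 0, ppm_noise_sd >= 0, rt_jitter_sd >= 0,
            unknown_feature_rate >= 0, n_planted >= 0,
            length(rt_range) == 2, rt_range[1] < rt_range[2])
  if (!setequal(names(class_proportions), strains)) {
    stop("class_proportions must be named by strain", call. = FALSE)
  }
  for (s in strains) {
    p <- class_proportions[[s]]
    if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
      stop("class proportions for strain '", s,
           "' must be non-negative and sum to 1", call. = FALSE)
    }
  }
  if (length(dropout_prob) == 1L) {
    dropout_prob <- stats::setNames(rep(dropout_prob, length(strains)),
                                    strains)
  }
  stopifnot(all(dropout_prob >= 0 & dropout_prob <= 1))
  structure(list(
    strains = strains, replicates = as.integer(replicates),
    n_lipids = as.integer(n_lipids),
    class_proportions = class_proportions,
    noise_cv = noise_cv, ppm_noise_sd = ppm_noise_sd,
    rt_jitter_sd = rt_jitter_sd,
    unknown_feature_rate = unknown_feature_rate,
    dropout_prob = dropout_prob, left_censor = isTRUE(left_censor),
    n_planted = as.integer(n_planted), planted_log2fc = planted_log2fc,
    rt_range = rt_range, base_log2_range = base_log2_range,
    spike_standards = isTRUE(spike_standards), seed = as.integer(seed)
  ), class = "sim_config")
}

# Deterministic per-stage child seed below 2^31.
child_seed <- function(seed, stage) {
  as.integer((as.double(seed) * 1000003 + stage) %% 2147483629)
}

#' Generate ground-truth lipids for a simulated experiment
#'
#' Samples `n_lipids` sum compositions from the bundled library so that
#' the expected lipid-class mix of each strain's expressed lipids
#' matches its configured proportions, assigns true retention times
#' (spaced so that near-isobaric lipids never coelute), baseline
#' intensities shared across strains, planted log2 fold changes on
#' `n_planted` lipids, and per-strain dropout probabilities. Unknown
#' features with no library counterpart are appended at
#' `unknown_feature_rate`.
#'
#' @param cfg A [sim_config()].
#' @param library Lipid library to draw identities from.
#' @return A `ground_truth` data.frame, one row per true chromatographic
#'   entity, with per-strain columns `expressed_*`, `base_*`
#'   (log2 scale) and `dropout_*`.
#' @export
generate_ground_truth <- function(cfg, library = default_lipid_library()) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(child_seed(cfg$seed, 1L))
  lib <- library[!library$is_standard, ]
  classes <- sort(unique(unlist(lapply(cfg$class_proportions, names))))
  prop <- matrix(0, length(classes), length(cfg$strains),
                 dimnames = list(classes, cfg$strains))
  for (s in cfg$strains) {
    p <- cfg$class_proportions[[s]][classes]
    p[is.na(p)] <- 0
    prop[, s] <- p
  }
  pooled <- rowMeans(prop)
  pooled <- pooled / sum(pooled)
  usable <- pooled > 0 & classes %in% lib$subclass
  if (!any(usable)) stop("no usable lipid class", call. = FALSE)
  pool_cls <- classes[usable]
  pool_p <- pooled[usable] / sum(pooled[usable])

  n <- cfg$n_lipids
  subclass <- sample(pool_cls, n, replace = TRUE, prob = pool_p)
  idx <- vapply(subclass, function(cl) {
    cand <- which(lib$subclass == cl)
    cand[sample.int(length(cand), 1L)]
  }, integer(1))
  truth <- data.frame(
    lipid_id = sprintf("L%04d", seq_len(n)),
    name = lib$name[idx], subclass = lib$subclass[idx],
    formula = lib$formula[idx],
    monoisotopic_mass = lib$monoisotopic_mass[idx],
    is_library = TRUE, unknown_mz = NA_real_,
    unknown_polarity = NA_character_,
    stringsAsFactors = FALSE
  )

  # expression: P(expressed in strain s | subclass c) chosen so the
  # expected composition of strain s's expressed lipids matches its
  # configured proportions
  for (s in cfg$strains) {
    ratio <- ifelse(pooled > 0, prop[, s] / pooled, 0)
    k <- if (max(ratio) > 0) 1 / max(ratio) else 0
    w <- stats::setNames(ratio * k, classes)
    truth[[paste0("expressed_", s)]] <-
      stats::runif(n) < w[truth$subclass]
  }

  # unknown features: mz > 10 ppm away from every library adduct target
  n_unknown <- round(cfg$unknown_feature_rate * n)
  if (n_unknown > 0) {
    targets <- library_adduct_targets(library)$mz_theoretical
    umz <- numeric(n_unknown)
    upol <- sample(c("positive", "negative"), n_unknown, replace = TRUE)
    for (i in seq_len(n_unknown)) {
      repeat {
        m <- stats::runif(1, 250, 900)
        if (all(abs(m - targets) / targets * 1e6 > 10)) break
      }
      umz[i] <- m
    }
    unk <- data.frame(
      lipid_id = sprintf("U%04d", seq_len(n_unknown)),
      name = sprintf("unknown_%03d", seq_len(n_unknown)),
      subclass = "unknown", formula = NA_character_,
      monoisotopic_mass = NA_real_, is_library = FALSE,
      unknown_mz = umz, unknown_polarity = upol,
      stringsAsFactors = FALSE
    )
    for (s in cfg$strains) {
      unk[[paste0("expressed_", s)]] <- stats::runif(n_unknown) < 0.8
    }
    truth <- rbind(truth, unk)
  }
  m <- nrow(truth)

  # retention times: near-isobaric entities are kept > 120 s apart so
  # true lipids map one-to-one onto aligned features; the spiked
  # standards occupy fixed slots and are avoided too
  key_mass <- ifelse(truth$is_library, truth$monoisotopic_mass,
                     truth$unknown_mz)
  fixed_mass <- numeric(0); fixed_rt <- numeric(0)
  if (cfg$spike_standards) {
    std <- internal_standards()
    fixed_mass <- std$monoisotopic_mass
    fixed_rt <- seq(cfg$rt_range[1] + 30, cfg$rt_range[2] - 30,
                    length.out = nrow(std))
  }
  rt_true <- numeric(m)
  for (i in seq_len(m)) {
    clash <- which(abs(c(fixed_mass, key_mass[seq_len(i - 1L)]) -
                         key_mass[i]) < 0.1)
    taken <- c(fixed_rt, rt_true)[clash]
    for (try in 1:500) {
      r <- stats::runif(1, cfg$rt_range[1], cfg$rt_range[2])
      if (!length(clash) || all(abs(taken - r) > 120)) break
    }
    rt_true[i] <- r
  }
  truth$rt_true <- rt_true

  base <- stats::runif(m, cfg$base_log2_range[1], cfg$base_log2_range[2])
  for (s in cfg$strains) truth[[paste0("base_", s)]] <- base

  # planted effects: one strain shifted up by planted_log2fc
  truth$planted_strain <- NA_character_
  truth$planted_log2fc <- 0
  expressed <- as.matrix(truth[, paste0("expressed_", cfg$strains)])
  eligible <- which(rowSums(expressed) >= 2 & truth$is_library)
  n_planted <- min(cfg$n_planted, length(eligible))
  if (n_planted > 0) {
    chosen <- sample(eligible, n_planted)
    for (i in chosen) {
      on <- cfg$strains[expressed[i, ]]
      s <- on[sample.int(length(on), 1L)]
      truth$planted_strain[i] <- s
      truth$planted_log2fc[i] <- cfg$planted_log2fc
      col <- paste0("base_", s)
      truth[[col]][i] <- truth[[col]][i] + cfg$planted_log2fc
    }
  }
  for (s in cfg$strains) {
    truth[[paste0("dropout_", s)]] <- unname(cfg$dropout_prob[s])
  }
  class(truth) <- c("ground_truth", "data.frame")
  attr(truth, "sim_config") <- cfg
  truth
}

# All theoretical adduct m/z targets of a library (both polarities).
library_adduct_targets <- function(library, rules = adduct_rules()) {
  out <- list()
  for (pol in c("positive", "negative")) {
    add <- rule_adduct(library$subclass, pol, rules)
    keep <- !is.na(add)
    if (any(keep)) {
      out[[pol]] <- data.frame(
        name = library$name[keep], subclass = library$subclass[keep],
        monoisotopic_mass = library$monoisotopic_mass[keep],
        is_standard = library$is_standard[keep],
        polarity = pol, adduct = add[keep],
        mz_theoretical = adduct_mz(library$monoisotopic_mass[keep],
                                   add[keep]),
        stringsAsFactors = FALSE
      )
    }
  }
  rbind_all(out)
}

#' Simulate per-sample feature observations from a ground truth
#'
#' Each expressed lipid emits, per sample, one peak per adduct required
#' by its subclass rule, at the theoretical adduct m/z perturbed by a
#' truncated-Gaussian ppm error, with retention time jittered around
#' its true value. Log2 intensities are Gaussian around the per-strain
#' baseline (so intensities are log-normal) with the planted effects
#' included; the biological deviation is shared between the two adducts
#' of a lipid within one sample. Observations drop out independently
#' with the per-strain dropout probability. Internal standards are
#' spiked into every sample when configured.
#'
#' @param truth A `ground_truth` from [generate_ground_truth()].
#' @param cfg The matching [sim_config()].
#' @return A data.frame of observations (columns `sample_id`, `strain`,
#'   `polarity`, `mz`, `rt`, `intensity`).
#' @export
simulate_observations <- function(truth, cfg = attr(truth, "sim_config")) {
  stopifnot(inherits(truth, "ground_truth"), nrow(truth) > 0,
            inherits(cfg, "sim_config"))
  set.seed(child_seed(cfg$seed, 2L))
  sdlog2 <- log2(1 + cfg$noise_cv)
  rules <- adduct_rules()
  samples <- sample_sheet(cfg)

  # per-entity ion forms
  ion_rows <- lapply(seq_len(nrow(truth)), function(i) {
    if (truth$is_library[i]) {
      adds <- c(rule_adduct(truth$subclass[i], "positive", rules),
                rule_adduct(truth$subclass[i], "negative", rules))
      pols <- c("positive", "negative")[!is.na(adds)]
      adds <- adds[!is.na(adds)]
      data.frame(row = i, polarity = pols, adduct = adds,
                 mz_theoretical = adduct_mz(truth$monoisotopic_mass[i],
                                            adds),
                 stringsAsFactors = FALSE)
    } else {
      data.frame(row = i, polarity = truth$unknown_polarity[i],
                 adduct = NA_character_,
                 mz_theoretical = truth$unknown_mz[i],
                 stringsAsFactors = FALSE)
    }
  })
  ions <- do.call(rbind, ion_rows)
  # relative response of each ion form (constant across samples)
  ions$response <- 1
  second <- duplicated(ions$row)
  ions$response[second] <- stats::runif(sum(second), 0.3, 1)

  out <- vector("list", nrow(samples))
  # biological deviation per (entity, sample), shared across adducts
  dev <- matrix(stats::rnorm(nrow(truth) * nrow(samples), 0, sdlog2),
                nrow(truth), nrow(samples))
  for (j in seq_len(nrow(samples))) {
    s <- samples$strain[j]
    expr <- truth[[paste0("expressed_", s)]]
    sel <- ions[expr[ions$row], , drop = FALSE]
    if (!nrow(sel)) { out[[j]] <- empty_observations(); next }
    base <- truth[[paste0("base_", s)]][sel$row]
    log2_int <- base + dev[sel$row, j]
    intensity <- 2^log2_int * sel$response
    eps <- stats::rnorm(nrow(sel), 0, cfg$ppm_noise_sd)
    eps <- pmax(pmin(eps, 5), -5)
    mz <- sel$mz_theoretical * (1 + eps * 1e-6)
    rt <- pmax(0, truth$rt_true[sel$row] +
                    stats::rnorm(nrow(sel), 0, cfg$rt_jitter_sd))
    p_drop <- rep(truth[[paste0("dropout_", s)]][sel$row], length.out = nrow(sel))
    if (cfg$left_censor && any(p_drop > 0)) {
      lowcut <- stats::quantile(log2_int, 0.25)
      p_drop <- ifelse(log2_int < lowcut, pmin(1, 4 * p_drop), p_drop)
    }
    keep <- stats::runif(nrow(sel)) >= p_drop
    out[[j]] <- data.frame(
      sample_id = samples$sample_id[j], strain = s,
      polarity = sel$polarity, mz = mz, rt = rt,
      intensity = intensity, stringsAsFactors = FALSE
    )[keep, , drop = FALSE]
  }
  obs <- rbind_all(out)

  if (cfg$spike_standards) {
    std <- internal_standards()
    std_mz <- adduct_mz(std$monoisotopic_mass, std$qc_adduct)
    std_pol <- unname(.ADDUCT_POLARITY[normalize_adduct(std$qc_adduct)])
    std_rt <- seq(cfg$rt_range[1] + 30, cfg$rt_range[2] - 30,
                  length.out = nrow(std))
    ns <- nrow(std) * nrow(samples)
    eps <- pmax(pmin(stats::rnorm(ns, 0, cfg$ppm_noise_sd), 5), -5)
    spikes <- data.frame(
      sample_id = rep(samples$sample_id, each = nrow(std)),
      strain = rep(samples$strain, each = nrow(std)),
      polarity = rep(std_pol, nrow(samples)),
      mz = rep(std_mz, nrow(samples)) * (1 + eps * 1e-6),
      rt = pmax(0, rep(std_rt, nrow(samples)) +
                     stats::rnorm(ns, 0, cfg$rt_jitter_sd)),
      intensity = 2^(18 + stats::rnorm(ns, 0, sdlog2)),
      stringsAsFactors = FALSE
    )
    obs <- rbind(obs, spikes)
  }
  rownames(obs) <- NULL
  obs
}

#' Sample sheet implied by a simulation configuration
#'
#' @param cfg A [sim_config()].
#' @return Data.frame with `sample_id`, `strain`, `replicate_index`.
#' @export
sample_sheet <- function(cfg) {
  data.frame(
    sample_id = as.vector(t(outer(cfg$strains, seq_len(cfg$replicates),
                                  function(s, r) sprintf("%s_%d", s, r)))),
    strain = rep(cfg$strains, each = cfg$replicates),
    replicate_index = rep(seq_len(cfg$replicates), length(cfg$strains)),
    stringsAsFactors = FALSE
  )
}

#' Write a simulated fixture to disk
#'
#' Writes `observations.csv` (feature-table dialect), `truth.tsv` and
#' `simconfig.yaml` into `dir`. Regeneration with the same seed yields
#' byte-identical files.
#'
#' @param observations,truth,cfg Simulator outputs.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture <- function(observations, truth, dir,
                          cfg = attr(truth, "sim_config")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_feature_table(observations, file.path(dir, "observations.csv"))
  tr <- as.data.frame(truth)
  num <- vapply(tr, is.numeric, logical(1))
  for (k in names(tr)[num]) tr[[k]] <- sprintf("%.6f", tr[[k]])
  utils::write.table(tr, file.path(dir, "truth.tsv"), sep = "\t",
                     row.names = FALSE, quote = FALSE)
  cfg_out <- unclass(cfg)
  cfg_out$class_proportions <- lapply(cfg_out$class_proportions, as.list)
  cfg_out$dropout_prob <- as.list(cfg_out$dropout_prob)
  yaml::write_yaml(cfg_out, file.path(dir, "simconfig.yaml"))
  invisible(dir)
}

#' Map aligned consensus features back to ground-truth entities
#'
#' Utility for scoring recovery: each consensus feature is matched to
#' the ground-truth ion whose theoretical m/z is within `ppm_tol` and
#' whose true retention time is within `rt_tol` (nearest m/z wins).
#'
#' @param truth A `ground_truth`.
#' @param features Feature table (columns `polarity`, `mz`, `rt`), e.g.
#'   `feature_matrix$features`.
#' @param ppm_tol,rt_tol Matching gates.
#' @return Character vector of `lipid_id` (NA where unmatched), aligned
#'   with the rows of `features`.
#' @export
match_truth <- function(truth, features, ppm_tol = 10, rt_tol = 60) {
  rules <- adduct_rules()
  ion_list <- lapply(seq_len(nrow(truth)), function(i) {
    if (truth$is_library[i]) {
      adds <- c(rule_adduct(truth$subclass[i], "positive", rules),
                rule_adduct(truth$subclass[i], "negative", rules))
      pols <- c("positive", "negative")[!is.na(adds)]
      adds <- adds[!is.na(adds)]
      if (!length(adds)) return(NULL)
      data.frame(lipid_id = truth$lipid_id[i], polarity = pols,
                 mz = adduct_mz(truth$monoisotopic_mass[i], adds),
                 rt = truth$rt_true[i], stringsAsFactors = FALSE)
    } else {
      data.frame(lipid_id = truth$lipid_id[i],
                 polarity = truth$unknown_polarity[i],
                 mz = truth$unknown_mz[i], rt = truth$rt_true[i],
                 stringsAsFactors = FALSE)
    }
  })
  ions <- do.call(rbind, ion_list)
  vapply(seq_len(nrow(features)), function(k) {
    cand <- ions$polarity == features$polarity[k] &
      abs(ions$mz - features$mz[k]) / ions$mz * 1e6 <= ppm_tol &
      abs(ions$rt - features$rt[k]) <= rt_tol
    if (!any(cand)) return(NA_character_)
    hit <- which(cand)
    hit <- hit[which.min(abs(ions$mz[hit] - features$mz[k]))]
    ions$lipid_id[hit]
  }, character(1))
}
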