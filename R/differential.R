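# Per-feature two-group statistics, Storey q-values, fold changes and
# volcano classification.

# Vectorized OLS of log intensity on a two-level group indicator.
# Returns the two-sided p-value of the group coefficient; with pooled
# variance this is the classical equal-variance two-sample comparison.
group_lm_pvalues <- function(x, group, welch = FALSE) {
  group <- as.factor(group)
  stopifnot(nlevels(group) == 2L, ncol(x) == length(group))
  ia <- group == levels(group)[1L]
  na <- sum(ia); nb <- sum(!ia)
  stopifnot(na >= 2L, nb >= 2L)
  xa <- x[, ia, drop = FALSE]; xb <- x[, !ia, drop = FALSE]
  ma <- rowMeans(xa); mb <- rowMeans(xb)
  ssa <- rowSums((xa - ma)^2); ssb <- rowSums((xb - mb)^2)
  beta <- ma - mb
  if (welch) {
    va <- ssa / (na - 1L); vb <- ssb / (nb - 1L)
    se2 <- va / na + vb / nb
    df <- se2^2 / ((va / na)^2 / (na - 1L) + (vb / nb)^2 / (nb - 1L))
  } else {
    s2 <- (ssa + ssb) / (na + nb - 2L)
    se2 <- s2 * (1 / na + 1 / nb)
    df <- rep(na + nb - 2L, length(beta))
  }
  p <- rep(NA_real_, length(beta))
  degenerate <- se2 <= .Machine$double.eps * pmax(ma^2, 1)
  if (any(degenerate)) {
    zero_effect <- degenerate & abs(beta) <= .Machine$double.eps * 100
    p[degenerate] <- ifelse(zero_effect[degenerate], 1, 0)
    if (any(degenerate & !zero_effect)) {
      warning(sum(degenerate & !zero_effect),
              " feature(s) with zero residual variance but nonzero ",
              "effect; p set to 0", call. = FALSE)
    }
  }
  ok <- !degenerate
  tstat <- beta[ok] / sqrt(se2[ok])
  p[ok] <- 2 * stats::pt(-abs(tstat), df[ok])
  p
}

#' Per-feature regression p-values for a strain pair
#'
#' Fits, per feature, a linear model of log2 normalized intensity on
#' the two-level strain indicator and returns the two-sided p-value of
#' the strain coefficient (equivalent to a pooled-variance two-sample
#' comparison; Welch available via `welch = TRUE`).
#'
#' @param ds A `pairwise_dataset` at stage `"normalized"`.
#' @param welch Use Welch (unequal-variance) statistics.
#' @param log_base Log base for the transform (default 2).
#' @return Named numeric vector of p-values (names = feature ids).
#' @export
feature_pvalues <- function(ds, welch = FALSE, log_base = 2) {
  require_stage(ds, "normalized")
  x <- log(ds$values, base = log_base)
  grp <- factor(ds$samples$strain, levels = c(ds$strain_a, ds$strain_b))
  p <- group_lm_pvalues(x, grp, welch = welch)
  stats::setNames(p, ds$features$feature_id)
}

#' Storey pi0 estimate
#'
#' Estimates the proportion of true nulls from a p-value vector:
#' `pi0(lambda) = #\{p > lambda\} / (m (1 - lambda))` on the grid
#' `lambda = 0.05, 0.10, ..., 0.95`, smoothed with a cubic smoothing
#' spline (3 df) and read off at `lambda = 0.95`, clipped to (0, 1].
#' With fewer than 100 p-values the spline is unstable and the
#' estimate falls back to 1 with a warning.
#'
#' @param p P-values in [0, 1].
#' @return The pi0 estimate (scalar in (0, 1]).
#' @export
storey_pi0 <- function(p) {
  stopifnot(all(p >= 0 & p <= 1))
  m <- length(p)
  if (m < 100L) {
    warning("fewer than 100 p-values; pi0 set to 1", call. = FALSE)
    return(1)
  }
  lambda <- seq(0.05, 0.95, by = 0.05)
  pi0_l <- vapply(lambda, function(l) sum(p > l) / (m * (1 - l)),
                  numeric(1))
  fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
  pi0 <- stats::predict(fit, x = 0.95)$y
  min(max(pi0, .Machine$double.eps), 1)
}

#' Storey q-values
#'
#' False discovery rate q-values: the BH-style step-up quantity scaled
#' by the estimated null proportion pi0,
#' `q_i = min over \{j : p_j >= p_i\} of pi0 * m * p_j / rank(p_j)`,
#' capped at 1. With `pi0 = 1` this reduces exactly to
#' Benjamini-Hochberg adjusted p-values. Order-preserving in p.
#'
#' @param p P-values in [0, 1].
#' @param pi0 Null-proportion override; `NULL` (default) estimates it
#'   with [storey_pi0()].
#' @return Numeric vector of q-values aligned with `p` (names kept).
#' @export
storey_qvalues <- function(p, pi0 = NULL) {
  if (any(p < 0 | p > 1)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  m <- length(p)
  stopifnot(m >= 1L)
  if (is.null(pi0)) pi0 <- storey_pi0(p)
  stopifnot(pi0 > 0, pi0 <= 1)
  o <- order(p, decreasing = TRUE)
  ro <- integer(m); ro[o] <- seq_len(m)
  q <- pmin(1, cummin(pi0 * m / (m:1) * p[o]))[ro]
  names(q) <- names(p)
  q
}

#' Fold changes between the two strains of a pair
#'
#' `fc = mean(strain_a) / mean(strain_b)` on the (back-transformed)
#' normalized intensity scale; `strain_a` is the first-named comparison
#' member. Arithmetic group means by default; geometric via
#' `geometric = TRUE`.
#'
#' @param ds A `pairwise_dataset` at stage `"normalized"`.
#' @param geometric Use geometric means.
#' @return Named numeric vector of linear-scale fold changes.
#' @export
fold_changes <- function(ds, geometric = FALSE) {
  require_stage(ds, "normalized")
  ia <- ds$samples$strain == ds$strain_a
  va <- ds$values[, ia, drop = FALSE]
  vb <- ds$values[, !ia, drop = FALSE]
  if (geometric) {
    fc <- exp(rowMeans(log(va)) - rowMeans(log(vb)))
  } else {
    mb <- rowMeans(vb)
    if (any(mb <= 0)) {
      stop("internal consistency error: non-positive group mean after ",
           "imputation", call. = FALSE)
    }
    fc <- rowMeans(va) / mb
  }
  stats::setNames(fc, ds$features$feature_id)
}

#' Classify features for the volcano plot
#'
#' A feature is significant iff `p < p_threshold` (strict) AND
#' (`fc > fc_upper` OR `fc < fc_lower`, strict). Direction is `"up"`
#' when `fc > fc_upper`, `"down"` when `fc < fc_lower`, else `"none"`.
#' The q-value is reported alongside but is not part of the gate.
#'
#' @param ds A `pairwise_dataset` at stage `"normalized"`.
#' @param pvalues,qvalues,fcs Named vectors covering the dataset's
#'   features.
#' @param cfg A [pipeline_config()] carrying the thresholds.
#' @return A `differential_results` data.frame: `feature_id`,
#'   `polarity`, `mz`, `rt`, `fc`, `log2_fc`, `p`, `q`, `significant`,
#'   `direction`.
#' @export
classify_features <- function(ds, pvalues, qvalues, fcs,
                              cfg = pipeline_config()) {
  require_stage(ds, "normalized")
  ids <- ds$features$feature_id
  for (nm in list(pvalues, qvalues, fcs)) {
    if (!all(ids %in% names(nm))) {
      stop("statistics missing for feature(s): ",
           paste(utils::head(setdiff(ids, names(nm)), 3), collapse = ", "),
           call. = FALSE)
    }
  }
  p <- unname(pvalues[ids]); q <- unname(qvalues[ids])
  fc <- unname(fcs[ids])
  direction <- ifelse(fc > cfg$fc_upper, "up",
                      ifelse(fc < cfg$fc_lower, "down", "none"))
  res <- data.frame(
    feature_id = ids,
    polarity = ds$features$polarity,
    mz = ds$features$mz, rt = ds$features$rt,
    fc = fc, log2_fc = log2(fc), p = p, q = q,
    significant = p < cfg$p_threshold & direction != "none",
    direction = direction,
    stringsAsFactors = FALSE
  )
  attr(res, "comparison") <- c(ds$strain_a, ds$strain_b)
  class(res) <- c("differential_results", "data.frame")
  res
}

#' Run statistics on a normalized strain pair
#'
#' Convenience wrapper: [feature_pvalues()], [storey_qvalues()],
#' [fold_changes()], [classify_features()].
#'
#' @param ds A `pairwise_dataset` at stage `"normalized"`.
#' @param cfg A [pipeline_config()].
#' @return A `differential_results` data.frame.
#' @export
differential_analysis <- function(ds, cfg = pipeline_config()) {
  p <- feature_pvalues(ds, welch = cfg$welch, log_base = cfg$log_base)
  q <- storey_qvalues(p)
  fc <- fold_changes(ds, geometric = cfg$geometric_fc)
  classify_features(ds, p, q, fc, cfg)
}

#' Export a volcano table
#'
#' Tab-delimited table with one row per feature (`feature_id`, `mz`,
#' `rt_seconds`, `log2_fc`, `neg_log10_p`, `q`, `class`, `annotation`)
#' followed by a footer comment line
#' `# total=<n> significant=<n>`.
#'
#' @param results A `differential_results` data.frame.
#' @param path Output path.
#' @param annotations Optional annotation table; confirmed lipid names
#'   (with isomer suffix) are joined on `feature_id`.
#' @return `path`, invisibly.
#' @export
volcano_export <- function(results, path, annotations = NULL) {
  stopifnot(nrow(results) > 0)
  ann <- rep("", nrow(results))
  if (!is.null(annotations) && nrow(annotations)) {
    conf <- annotations[annotations$confirmed, , drop = FALSE]
    if (nrow(conf)) {
      lab <- ifelse(nzchar(conf$isomer_label),
                    paste0(conf$name, " isomer ", conf$isomer_label),
                    conf$name)
      first <- !duplicated(conf$feature_id)
      ann_map <- stats::setNames(lab[first], conf$feature_id[first])
      hit <- results$feature_id %in% names(ann_map)
      ann[hit] <- unname(ann_map[results$feature_id[hit]])
    }
  }
  out <- data.frame(
    feature_id = results$feature_id,
    mz = sprintf("%.6f", results$mz),
    rt_seconds = sprintf("%.3f", results$rt),
    log2_fc = sprintf("%.6f", results$log2_fc),
    neg_log10_p = sprintf("%.6f", -log10(pmax(results$p, 1e-300))),
    q = sprintf("%.6g", results$q),
    class = ifelse(results$significant,
                   paste0("significant_", results$direction), "ns"),
    annotation = ann,
    stringsAsFactors = FALSE
  )
  con <- file(path, "w")
  on.exit(close(con))
  utils::write.table(out, con, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  writeLines(sprintf("# total=%d significant=%d", nrow(results),
                     sum(results$significant)), con)
  invisible(path)
}
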