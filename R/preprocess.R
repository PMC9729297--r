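# Strain-pair preprocessing: the dataset is split into two-strain
# slices, then filtered, imputed and normalized in that order.
#
# Stage order is enforced: raw -> filtered -> imputed -> normalized.
# The 100%-missing filter runs first and parks one-strain-only
# features as "exclusives" for qualitative presence/absence reporting;
# they never enter the statistics.

#' Build a two-strain slice of the feature matrix
#'
#' @param fm A `feature_matrix`.
#' @param strain_a,strain_b Strain labels; `strain_a` is the first-named
#'   comparison member and the fold-change numerator.
#' @return An object of class `pairwise_dataset` at stage `"raw"`.
#' @export
build_pairwise <- function(fm, strain_a, strain_b) {
  stopifnot(inherits(fm, "feature_matrix"))
  for (s in c(strain_a, strain_b)) {
    if (!s %in% fm$samples$strain) {
      stop("unknown strain label '", s, "'", call. = FALSE)
    }
  }
  if (strain_a == strain_b) stop("strains must differ", call. = FALSE)
  keep <- fm$samples$strain %in% c(strain_a, strain_b)
  samples <- fm$samples[keep, , drop = FALSE]
  rownames(samples) <- NULL
  structure(list(
    strain_a = strain_a, strain_b = strain_b,
    features = fm$features,
    samples = samples,
    values = fm$values[, samples$sample_id, drop = FALSE],
    raw_values = fm$values[, samples$sample_id, drop = FALSE],
    stage = "raw",
    exclusives = NULL
  ), class = "pairwise_dataset")
}

require_stage <- function(ds, stage) {
  stopifnot(inherits(ds, "pairwise_dataset"))
  if (!identical(ds$stage, stage)) {
    stop("expected a pairwise dataset at stage '", stage, "', got '",
         ds$stage, "'", call. = FALSE)
  }
  invisible(ds)
}

strain_presence <- function(ds) {
  a <- ds$samples$sample_id[ds$samples$strain == ds$strain_a]
  b <- ds$samples$sample_id[ds$samples$strain == ds$strain_b]
  obs <- !is.na(ds$values)
  list(a = rowSums(obs[, a, drop = FALSE]),
       b = rowSums(obs[, b, drop = FALSE]),
       n_a = length(a), n_b = length(b))
}

#' Remove features entirely missing in one strain
#'
#' Features with zero observed values in either strain of the pair are
#' moved to the `exclusives` slot (kept for qualitative
#' presence/absence reporting, e.g. a lipid absent from one strain);
#' all remaining features have at least one observation in each
#' strain.
#'
#' @param ds A `pairwise_dataset` at stage `"raw"`.
#' @return The dataset, still at stage `"raw"` completion step one
#'   (stage stays `"raw"` until the presence filter runs).
#' @export
filter_total_missing <- function(ds) {
  require_stage(ds, "raw")
  p <- strain_presence(ds)
  excl <- p$a == 0 | p$b == 0
  new_excl <- list(
    features = ds$features[excl, , drop = FALSE],
    values = ds$values[excl, , drop = FALSE],
    presence = data.frame(
      feature_id = ds$features$feature_id[excl],
      present_a = p$a[excl], n_a = rep(p$n_a, sum(excl)),
      present_b = p$b[excl], n_b = rep(p$n_b, sum(excl)),
      only_in = ifelse(p$a[excl] == 0 & p$b[excl] == 0, "neither",
                       ifelse(p$a[excl] == 0, ds$strain_b, ds$strain_a)),
      stringsAsFactors = FALSE
    )
  )
  if (is.null(ds$exclusives)) {
    ds$exclusives <- new_excl
  } else {  # re-application accumulates; nothing new qualifies anyway
    ds$exclusives$features <- rbind(ds$exclusives$features,
                                    new_excl$features)
    ds$exclusives$values <- rbind(ds$exclusives$values, new_excl$values)
    ds$exclusives$presence <- rbind(ds$exclusives$presence,
                                    new_excl$presence)
  }
  ds$features <- ds$features[!excl, , drop = FALSE]
  ds$values <- ds$values[!excl, , drop = FALSE]
  ds$raw_values <- ds$raw_values[!excl, , drop = FALSE]
  ds$total_missing_done <- TRUE
  ds
}

#' Keep features present in at least 80% of one strain's replicates
#'
#' A feature is kept iff it is observed in at least
#' `ceiling(threshold * n)` samples of at least one strain (n = that
#' strain's replicate count; with n = 6 and threshold 0.8 this means
#' >= 5 of 6).
#'
#' @param ds A `pairwise_dataset` after [filter_total_missing()].
#' @param threshold Presence fraction (default 0.8).
#' @return The dataset at stage `"filtered"`.
#' @export
filter_presence <- function(ds, threshold = 0.8) {
  stopifnot(inherits(ds, "pairwise_dataset"))
  if (!ds$stage %in% c("raw", "filtered")) {
    stop("filter_presence() expects stage 'raw' or 'filtered', got '",
         ds$stage, "'", call. = FALSE)
  }
  if (!isTRUE(ds$total_missing_done)) {
    stop("apply filter_total_missing() before filter_presence()",
         call. = FALSE)
  }
  stopifnot(threshold > 0, threshold <= 1)
  p <- strain_presence(ds)
  keep <- p$a >= ceiling(threshold * p$n_a) |
          p$b >= ceiling(threshold * p$n_b)
  ds$features <- ds$features[keep, , drop = FALSE]
  ds$values <- ds$values[keep, , drop = FALSE]
  ds$raw_values <- ds$raw_values[keep, , drop = FALSE]
  ds$stage <- "filtered"
  ds
}

#' Impute missing cells at a fraction of the per-feature minimum
#'
#' Every missing cell of a feature becomes
#' `factor x min(observed intensities of that feature)` within the
#' pairwise dataset; observed cells are untouched.
#'
#' @param ds A `pairwise_dataset` at stage `"filtered"`.
#' @param factor Fraction of the per-feature minimum (default 0.9).
#' @return The dataset at stage `"imputed"`, with no missing cells.
#' @export
impute_missing <- function(ds, factor = 0.9) {
  require_stage(ds, "filtered")
  stopifnot(factor > 0)
  v <- ds$values
  if (nrow(v)) {
    if (any(rowSums(!is.na(v)) == 0)) {
      stop("internal consistency error: feature with no observed values ",
           "survived filtering", call. = FALSE)
    }
    mins <- apply(v, 1L, min, na.rm = TRUE)
    miss <- which(is.na(v), arr.ind = TRUE)
    v[miss] <- factor * mins[miss[, 1L]]
  }
  ds$values <- v
  ds$stage <- "imputed"
  ds
}

#' Cyclic loess normalization on log-scale intensities
#'
#' Intensities are log2-transformed and normalized by full-pairwise
#' cyclic loess: for each ordered sample pair, a locally weighted
#' regression of the log-ratio M on the average log-intensity A
#' (tri-cube weights, degree 1) is fitted and half the fitted trend is
#' subtracted from one sample and added to the other; the pass over
#' all pairs is repeated `iterations` times. The result is
#' back-transformed to the intensity scale. Delegates to
#' [limma::normalizeCyclicLoess()] with `method = "pairs"`, the
#' reference implementation of this procedure. The grand mean of log
#' intensities is conserved by construction.
#'
#' @param ds A `pairwise_dataset` at stage `"imputed"` (all intensities
#'   strictly positive).
#' @param span Loess span (default 0.7).
#' @param iterations Full passes over all sample pairs (default 3).
#' @param log_base Base of the log transform (default 2).
#' @return The dataset at stage `"normalized"`, back on the intensity
#'   scale.
#' @export
cyclic_loess_normalize <- function(ds, span = 0.7, iterations = 3,
                                   log_base = 2) {
  require_stage(ds, "imputed")
  v <- ds$values
  if (any(v <= 0)) {
    stop("non-positive intensity at normalization stage", call. = FALSE)
  }
  if (nrow(v) >= 2L && ncol(v) >= 2L) {
    lv <- log(v, base = log_base)
    lnorm <- limma::normalizeCyclicLoess(lv, span = span,
                                         iterations = iterations,
                                         method = "pairs")
    dimnames(lnorm) <- dimnames(v)
    v <- log_base^lnorm
  }
  ds$values <- v
  ds$stage <- "normalized"
  ds
}

#' Run the full preprocessing chain on one strain pair
#'
#' [filter_total_missing()], [filter_presence()], [impute_missing()]
#' and [cyclic_loess_normalize()] in order, with parameters taken from
#' a [pipeline_config()].
#'
#' @param ds A `pairwise_dataset` at stage `"raw"`.
#' @param cfg A [pipeline_config()].
#' @return The dataset at stage `"normalized"`.
#' @export
preprocess_pairwise <- function(ds, cfg = pipeline_config()) {
  ds <- filter_total_missing(ds)
  ds <- filter_presence(ds, cfg$presence_threshold)
  ds <- impute_missing(ds, cfg$imputation_factor)
  cyclic_loess_normalize(ds, span = cfg$loess_span,
                         iterations = cfg$loess_iterations,
                         log_base = cfg$log_base)
}

#' @export
print.pairwise_dataset <- function(x, ...) {
  cat(sprintf("Pairwise dataset %s vs %s [stage: %s]: %d features x %d samples",
              x$strain_a, x$strain_b, x$stage, nrow(x$features),
              nrow(x$samples)))
  if (!is.null(x$exclusives)) {
    cat(sprintf("; %d exclusive features", nrow(x$exclusives$features)))
  }
  cat("\n")
  invisible(x)
}
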