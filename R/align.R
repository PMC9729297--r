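# Chromatographic run alignment: collapse per-run peaks into consensus
# features across all samples of one polarity.

#' Align observations of one polarity into consensus features
#'
#' Greedy median-anchored clustering: observations are sorted by m/z
#' and each joins the open group whose running median m/z is within
#' `ppm_tol` and running median retention time within `rt_tol` (closest
#' m/z wins when several qualify). If the group already holds a peak
#' from the same sample, the more intense peak is kept and the other
#' seeds a new group. Consensus m/z and RT are member medians; the
#' result is sorted by (m/z, RT) and is deterministic.
#'
#' @param observations Observation data.frame, single polarity.
#' @param ppm_tol m/z gate in ppm (default 5).
#' @param rt_tol Retention-time gate in seconds (default 15).
#' @return An object of class `consensus_features`: list with
#'   `features` (feature-level data.frame: `polarity`, `mz`, `rt`,
#'   `n_samples`) and `members` (per-observation assignments with
#'   `feature_idx`).
#' @export
align_runs <- function(observations, ppm_tol = 5, rt_tol = 15) {
  pol <- unique(observations$polarity)
  if (length(pol) > 1) {
    stop("align_runs() expects a single polarity; got: ",
         paste(pol, collapse = ", "), call. = FALSE)
  }
  n <- nrow(observations)
  if (n == 0L) {
    return(structure(list(
      features = data.frame(polarity = character(), mz = numeric(),
                            rt = numeric(), n_samples = integer()),
      members = cbind(empty_observations(), feature_idx = integer())
    ), class = "consensus_features"))
  }
  ord <- order(observations$mz, observations$rt,
               -observations$intensity, observations$sample_id)
  obs <- observations[ord, , drop = FALSE]

  grp_mz <- numeric(0)      # running median m/z per group
  grp_rt <- numeric(0)      # running median RT per group
  members <- list()         # member row indices (into obs) per group
  assign_of <- integer(n)
  active_lo <- 1L           # groups below this index can never match again

  place <- function(i, exclude = 0L) {
    g <- length(grp_mz)
    mz_i <- obs$mz[i]
    # retire groups that have fallen outside any possible ppm window
    while (active_lo <= g &&
           grp_mz[active_lo] < mz_i * (1 - 3 * ppm_tol * 1e-6)) {
      active_lo <<- active_lo + 1L
    }
    best <- 0L; best_d <- Inf
    if (active_lo <= g) {
      for (k in active_lo:g) {
        if (k == exclude) next
        d <- abs(mz_i - grp_mz[k]) / grp_mz[k] * 1e6
        if (d <= ppm_tol && abs(obs$rt[i] - grp_rt[k]) <= rt_tol &&
            d < best_d) {
          best <- k; best_d <- d
        }
      }
    }
    if (best == 0L) {
      grp_mz[g + 1L] <<- mz_i
      grp_rt[g + 1L] <<- obs$rt[i]
      members[[g + 1L]] <<- i
      assign_of[i] <<- g + 1L
      return(invisible())
    }
    mem <- members[[best]]
    same <- mem[obs$sample_id[mem] == obs$sample_id[i]]
    if (length(same)) {
      if (obs$intensity[i] > obs$intensity[same[1]]) {
        # replace the weaker peak; the displaced one seeds a new group
        mem <- c(setdiff(mem, same[1]), i)
        members[[best]] <<- mem
        assign_of[i] <<- best
        grp_mz[best] <<- stats::median(obs$mz[mem])
        grp_rt[best] <<- stats::median(obs$rt[mem])
        displaced <- same[1]
        g2 <- length(grp_mz)
        grp_mz[g2 + 1L] <<- obs$mz[displaced]
        grp_rt[g2 + 1L] <<- obs$rt[displaced]
        members[[g2 + 1L]] <<- displaced
        assign_of[displaced] <<- g2 + 1L
      } else {
        g2 <- length(grp_mz)
        grp_mz[g2 + 1L] <<- mz_i
        grp_rt[g2 + 1L] <<- obs$rt[i]
        members[[g2 + 1L]] <<- i
        assign_of[i] <<- g2 + 1L
      }
    } else {
      mem <- c(mem, i)
      members[[best]] <<- mem
      assign_of[i] <<- best
      grp_mz[best] <<- stats::median(obs$mz[mem])
      grp_rt[best] <<- stats::median(obs$rt[mem])
    }
    invisible()
  }
  for (i in seq_len(n)) place(i)

  feat <- data.frame(polarity = pol,
                     mz = grp_mz, rt = grp_rt,
                     n_samples = lengths(members))
  ford <- order(feat$mz, feat$rt)
  feat <- feat[ford, , drop = FALSE]
  rownames(feat) <- NULL
  remap <- integer(length(ford)); remap[ford] <- seq_along(ford)
  mem_out <- obs
  mem_out$feature_idx <- remap[assign_of]
  mem_out <- mem_out[order(mem_out$feature_idx, mem_out$sample_id), ,
                     drop = FALSE]
  rownames(mem_out) <- NULL
  structure(list(features = feat, members = mem_out),
            class = "consensus_features")
}

#' Build the aligned feature x sample intensity matrix
#'
#' Rows are consensus features (positive polarity block first, tagged
#' by polarity), columns are samples; cells hold the member peak
#' intensity or `NA` where a sample contributed no peak.
#'
#' @param consensus_pos,consensus_neg `consensus_features` for the two
#'   polarities (either may be empty).
#' @param samples Sample sheet (`sample_id`, `strain`,
#'   `replicate_index`).
#' @return An object of class `feature_matrix`: list with `features`
#'   (`feature_id`, `polarity`, `mz`, `rt`), `samples`, and `values`
#'   (numeric matrix, `NA` = missing).
#' @export
build_matrix <- function(consensus_pos, consensus_neg, samples) {
  if (anyDuplicated(samples$sample_id)) {
    stop("duplicate sample_id in sample sheet", call. = FALSE)
  }
  if (anyDuplicated(samples[, c("strain", "replicate_index")])) {
    stop("duplicate (strain, replicate_index) in sample sheet",
         call. = FALSE)
  }
  blocks <- list(positive = consensus_pos, negative = consensus_neg)
  feats <- list(); rows <- list()
  for (pol in names(blocks)) {
    cf <- blocks[[pol]]
    if (is.null(cf) || nrow(cf$features) == 0L) next
    stopifnot(inherits(cf, "consensus_features"))
    unknown <- setdiff(unique(cf$members$sample_id), samples$sample_id)
    if (length(unknown)) {
      stop("observations reference unknown sample(s): ",
           paste(unknown, collapse = ", "), call. = FALSE)
    }
    tag <- if (pol == "positive") "P" else "N"
    f <- cf$features
    f$feature_id <- sprintf("%s%05d", tag, seq_len(nrow(f)))
    feats[[pol]] <- f[, c("feature_id", "polarity", "mz", "rt")]
    vals <- matrix(NA_real_, nrow(f), nrow(samples),
                   dimnames = list(f$feature_id, samples$sample_id))
    idx <- cbind(cf$members$feature_idx,
                 match(cf$members$sample_id, samples$sample_id))
    vals[idx] <- cf$members$intensity
    rows[[pol]] <- vals
  }
  features <- rbind_all(feats)
  values <- do.call(rbind, rows)
  if (is.null(features)) {
    features <- data.frame(feature_id = character(),
                           polarity = character(), mz = numeric(),
                           rt = numeric())
    values <- matrix(numeric(), 0, nrow(samples),
                     dimnames = list(NULL, samples$sample_id))
  }
  stopifnot(all(values >= 0, na.rm = TRUE))
  structure(list(features = features, samples = samples,
                 values = values),
            class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  cat(sprintf(
    "Feature matrix: %d features (%d positive, %d negative) x %d samples; %.1f%% missing\n",
    nrow(x$features), sum(x$features$polarity == "positive"),
    sum(x$features$polarity == "negative"), nrow(x$samples),
    100 * mean(is.na(x$values))))
  invisible(x)
}
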