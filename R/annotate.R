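# Accurate-mass annotation with cross-polarity coelution confirmation,
# isomer labelling, and strain-level lipid-class composition.

#' Match consensus features against a lipid library by accurate mass
#'
#' For every feature, each (lipid, adduct) pair whose theoretical
#' adduct m/z — per the lipid subclass's rule for the feature's
#' polarity — lies strictly within `ppm_tol` is emitted as a
#' candidate. Subclasses with no ion form in the feature's polarity
#' are skipped. Candidates are sorted by ascending ppm error within a
#' feature; nothing is confirmed at this stage.
#'
#' @param features Feature table with `feature_id`, `polarity`, `mz`,
#'   `rt` (e.g. `feature_matrix$features`).
#' @param library Lipid library data.frame.
#' @param rules Adduct rule table (default [adduct_rules()]).
#' @param ppm_tol Mass gate in ppm (default 5, strict).
#' @return An `annotations` data.frame: `feature_id`, `polarity`, `mz`,
#'   `rt`, `name`, `subclass`, `adduct`, `mz_theoretical`, `ppm`,
#'   `confirmed` (all `FALSE`), `partner_feature_id` (`NA`),
#'   `isomer_label` (`""`).
#' @export
match_library <- function(features, library, rules = adduct_rules(),
                          ppm_tol = 5) {
  stopifnot(all(library$monoisotopic_mass > 0))
  targets <- library_adduct_targets(library, rules)
  out <- vector("list", nrow(features))
  for (i in seq_len(nrow(features))) {
    t_pol <- targets[targets$polarity == features$polarity[i], ,
                     drop = FALSE]
    ppm <- abs(features$mz[i] - t_pol$mz_theoretical) /
      t_pol$mz_theoretical * 1e6
    hit <- which(ppm < ppm_tol)
    if (!length(hit)) next
    hit <- hit[order(ppm[hit])]
    out[[i]] <- data.frame(
      feature_id = features$feature_id[i],
      polarity = features$polarity[i],
      mz = features$mz[i], rt = features$rt[i],
      name = t_pol$name[hit], subclass = t_pol$subclass[hit],
      adduct = t_pol$adduct[hit],
      mz_theoretical = t_pol$mz_theoretical[hit],
      ppm = ppm[hit],
      is_standard = t_pol$is_standard[hit],
      stringsAsFactors = FALSE
    )
  }
  ann <- rbind_all(out)
  if (is.null(ann)) {
    ann <- data.frame(feature_id = character(), polarity = character(),
                      mz = numeric(), rt = numeric(), name = character(),
                      subclass = character(), adduct = character(),
                      mz_theoretical = numeric(), ppm = numeric(),
                      is_standard = logical(), stringsAsFactors = FALSE)
  }
  ann$confirmed <- logical(nrow(ann))
  ann$partner_feature_id <- rep(NA_character_, nrow(ann))
  ann$isomer_label <- rep("", nrow(ann))
  class(ann) <- c("annotations", "data.frame")
  ann
}

.DUAL_POLARITY_CLASSES <- c("FFA", "PE", "PG", "PC")
.SINGLE_POLARITY_CLASSES <- c("MGDG", "DGDG", "LPG")

#' Confirm annotations by cross-polarity coelution
#'
#' Dual-polarity subclasses (FFA, PE, PG, PC): a candidate is confirmed
#' iff some opposite-polarity candidate carries the same lipid with its
#' required opposite adduct and the two consensus retention times
#' differ by less than `rt_tol`; both partners are confirmed and
#' cross-linked (nearest RT wins when several partners qualify).
#' Single-polarity subclasses are confirmed on their one required ion:
#' MGDG/DGDG on `[M+NH4]+` alone, LPG on `[M-H]-` alone.
#'
#' @param candidates An `annotations` table from [match_library()].
#' @param rules Adduct rule table.
#' @param rt_tol Coelution window in seconds (default 30, strict).
#' @return The `annotations` table with `confirmed` and
#'   `partner_feature_id` filled in.
#' @export
cross_polarity_confirm <- function(candidates, rules = adduct_rules(),
                                   rt_tol = 30) {
  ann <- candidates
  if (!nrow(ann)) return(ann)
  single <- ann$subclass %in% .SINGLE_POLARITY_CLASSES
  ann$confirmed[single] <- TRUE
  dual <- which(ann$subclass %in% .DUAL_POLARITY_CLASSES)
  for (i in dual) {
    opp <- if (ann$polarity[i] == "positive") "negative" else "positive"
    need <- rule_adduct(ann$subclass[i], opp, rules)
    j <- which(ann$polarity == opp & ann$name == ann$name[i] &
               ann$adduct == need &
               abs(ann$rt - ann$rt[i]) < rt_tol)
    if (length(j)) {
      j <- j[which.min(abs(ann$rt[j] - ann$rt[i]))]
      ann$confirmed[i] <- TRUE
      ann$partner_feature_id[i] <- ann$feature_id[j]
    }
  }
  ann
}

#' Label coeluting-distinct isomers
#'
#' When two or more confirmed features within one polarity map to the
#' same lipid name, suffixes `a`, `b`, `c`, ... are assigned in
#' ascending retention-time order (ties broken by ascending m/z, then
#' feature id). Lipids confirmed on a single feature get no suffix.
#'
#' @param annotations An `annotations` table (typically after
#'   [cross_polarity_confirm()]).
#' @return The table with `isomer_label` filled for confirmed rows.
#' @export
label_isomers <- function(annotations) {
  ann <- annotations
  conf <- which(ann$confirmed)
  if (!length(conf)) return(ann)
  key <- paste(ann$name[conf], ann$polarity[conf], sep = "\r")
  for (k in unique(key)) {
    rows <- conf[key == k]
    feats <- unique(ann$feature_id[rows])
    if (length(feats) < 2L) next
    first <- rows[!duplicated(ann$feature_id[rows])]
    ord <- order(ann$rt[first], ann$mz[first], ann$feature_id[first])
    lab <- stats::setNames(letters[seq_along(ord)],
                           ann$feature_id[first][ord])
    ann$isomer_label[rows] <- unname(lab[ann$feature_id[rows]])
  }
  ann
}

#' Annotate aligned features end to end
#'
#' [match_library()], [cross_polarity_confirm()] and [label_isomers()]
#' in sequence.
#'
#' @param fm A `feature_matrix`.
#' @param library Lipid library.
#' @param cfg A [pipeline_config()] (ppm and RT gates).
#' @return An `annotations` data.frame.
#' @export
annotate_features <- function(fm, library = default_lipid_library(),
                              cfg = pipeline_config()) {
  cand <- match_library(fm$features, library,
                        ppm_tol = cfg$ppm_tolerance)
  cand <- cross_polarity_confirm(cand, rt_tol = cfg$rt_tolerance_s)
  label_isomers(cand)
}

#' Strain-level lipid-class composition
#'
#' Counts, per strain, the annotated lipids whose feature is observed
#' (non-missing, pre-imputation intensities) in at least
#' `ceiling(threshold x replicates)` of that strain's samples,
#' aggregated by subclass and normalized to proportions. A lipid
#' resolved into isomers counts once per labelled feature; a
#' cross-polarity-confirmed pair counts once. Internal standards are
#' excluded.
#'
#' @param fm The aligned `feature_matrix` (pre-imputation values).
#' @param annotations An `annotations` table; only confirmed rows are
#'   used when `confirmed_only` (default).
#' @param presence_threshold Presence fraction (default 0.8).
#' @param confirmed_only Restrict to cross-polarity-confirmed
#'   annotations.
#' @return A `composition_summary` data.frame: `strain`, `subclass`,
#'   `count`, `proportion`.
#' @export
strain_composition <- function(fm, annotations,
                               presence_threshold = 0.8,
                               confirmed_only = TRUE) {
  stopifnot(inherits(fm, "feature_matrix"))
  ann <- annotations
  if (confirmed_only) ann <- ann[ann$confirmed, , drop = FALSE]
  if ("is_standard" %in% names(ann)) {
    ann <- ann[!ann$is_standard, , drop = FALSE]
  }
  strains <- unique(fm$samples$strain)
  subclasses <- adduct_rules()$subclass
  if (!nrow(ann)) {
    warning("no confirmed annotations; composition summary is empty",
            call. = FALSE)
    return(structure(
      data.frame(strain = character(), subclass = character(),
                 count = integer(), proportion = numeric()),
      class = c("composition_summary", "data.frame")))
  }
  rowidx <- match(ann$feature_id, fm$features$feature_id)
  if (anyNA(rowidx)) {
    stop("annotation references feature absent from the matrix: ",
         ann$feature_id[is.na(rowidx)][1], call. = FALSE)
  }
  # one record per (lipid, isomer) entity; a confirmed pos/neg pair
  # collapses onto the same entity
  ann$entity <- paste(ann$name, ann$isomer_label, sep = "\r")
  out <- list()
  any_qualifies <- FALSE
  for (s in strains) {
    cols <- fm$samples$sample_id[fm$samples$strain == s]
    need <- ceiling(presence_threshold * length(cols))
    obs <- rowSums(!is.na(fm$values[rowidx, cols, drop = FALSE]))
    present <- obs >= need
    ents <- unique(ann$entity[present])
    sub_of <- ann$subclass[match(ents, ann$entity)]
    counts <- table(factor(sub_of, levels = subclasses))
    total <- sum(counts)
    if (total > 0) any_qualifies <- TRUE
    out[[s]] <- data.frame(
      strain = s, subclass = subclasses,
      count = as.integer(counts),
      proportion = if (total > 0) as.numeric(counts) / total
                   else rep(0, length(subclasses)),
      stringsAsFactors = FALSE
    )
  }
  if (!any_qualifies) {
    warning("no annotated lipid meets the presence threshold in any ",
            "strain", call. = FALSE)
  }
  res <- rbind_all(out)
  class(res) <- c("composition_summary", "data.frame")
  res
}

#' Internal-standard QC check
#'
#' Looks up each spiked internal standard at its QC ion form among the
#' aligned features of the matching polarity and reports whether it
#' was detected within the ppm gate, at what mass error, and in how
#' many samples.
#'
#' @param fm A `feature_matrix`.
#' @param standards Standards table (default [internal_standards()]).
#' @param ppm_tol Mass gate in ppm.
#' @return Data.frame: `name`, `adduct`, `polarity`, `detected`,
#'   `feature_id`, `ppm`, `n_samples`.
#' @export
qc_internal_standards <- function(fm, standards = internal_standards(),
                                  ppm_tol = 5) {
  mz_theo <- adduct_mz(standards$monoisotopic_mass, standards$qc_adduct)
  pol <- unname(.ADDUCT_POLARITY[normalize_adduct(standards$qc_adduct)])
  res <- data.frame(name = standards$name, adduct = standards$qc_adduct,
                    polarity = pol, detected = FALSE,
                    feature_id = NA_character_, ppm = NA_real_,
                    n_samples = 0L, stringsAsFactors = FALSE)
  for (i in seq_len(nrow(standards))) {
    cand <- which(fm$features$polarity == pol[i])
    if (!length(cand)) next
    ppm <- abs(fm$features$mz[cand] - mz_theo[i]) / mz_theo[i] * 1e6
    hit <- cand[ppm < ppm_tol]
    if (!length(hit)) next
    # a spiked standard is present in essentially every run; among
    # in-tolerance features take the best-covered one (isobaric
    # endogenous features are typically sparser), ties by ppm
    cover <- rowSums(!is.na(fm$values[hit, , drop = FALSE]))
    hppm <- ppm[match(hit, cand)]
    best <- order(-cover, hppm)[1]
    res$detected[i] <- TRUE
    res$feature_id[i] <- fm$features$feature_id[hit[best]]
    res$ppm[i] <- hppm[best]
    res$n_samples[i] <- cover[best]
  }
  res
}
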