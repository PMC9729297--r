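# End-to-end orchestration: read -> align -> pairwise preprocess ->
# statistics -> annotate -> composition -> run report.

default_comparisons <- function(strains) {
  # later-listed strain vs earlier-listed, plus the remaining pair
  # (for OP50, HA-114, R0011 this yields HA-114 vs OP50,
  # R0011 vs OP50, HA-114 vs R0011)
  n <- length(strains)
  out <- list()
  for (j in 2:n) out[[length(out) + 1L]] <- c(strains[j], strains[1])
  if (n >= 3) {
    for (j in 3:n) {
      for (i in 2:(j - 1)) {
        out[[length(out) + 1L]] <- c(strains[i], strains[j])
      }
    }
  }
  out
}

#' Run the full strain-contrast pipeline
#'
#' Aligns observations per polarity, builds the feature matrix, then
#' for every strain comparison applies the 100%-missing filter, the
#' presence filter, minimum-based imputation, cyclic loess
#' normalization and per-feature statistics; annotates aligned
#' features against the library with cross-polarity confirmation;
#' summarizes per-strain lipid-class composition; and checks the
#' internal standards. All intermediate tables are written when
#' `output_dir` is given.
#'
#' @param observations Observation data.frame (or a directory
#'   containing `observations.csv` in the feature-table dialect).
#' @param samples Sample sheet; derived from the observations when
#'   `NULL`.
#' @param cfg A [pipeline_config()].
#' @param library Lipid library for annotation.
#' @param comparisons List of `c(strain_a, strain_b)` pairs
#'   (`strain_a` = fold-change numerator); defaults to all pairs with
#'   the later-listed strain as numerator against the first strain.
#' @param output_dir Directory for artifacts (`NULL` = don't write).
#' @return A `run_report` list: `config`, `comparisons` (per-pair
#'   stage counts, results table, exclusives), `annotations`,
#'   `composition`, `standards_qc`, `matrix`.
#' @export
run_pipeline <- function(observations, samples = NULL,
                         cfg = pipeline_config(),
                         library = default_lipid_library(),
                         comparisons = NULL, output_dir = NULL) {
  if (is.character(observations) && length(observations) == 1L) {
    path <- if (dir.exists(observations)) {
      file.path(observations, "observations.csv")
    } else observations
    observations <- read_feature_table(path)
  }
  if (is.null(samples)) {
    u <- unique(observations[, c("sample_id", "strain")])
    u <- u[order(match(u$strain, unique(observations$strain)),
                 u$sample_id), ]
    samples <- data.frame(
      sample_id = u$sample_id, strain = u$strain,
      replicate_index = stats::ave(seq_len(nrow(u)), u$strain,
                                   FUN = seq_along),
      stringsAsFactors = FALSE
    )
  }
  strains <- unique(samples$strain)
  if (is.null(comparisons)) comparisons <- default_comparisons(strains)

  cons <- list()
  for (pol in c("positive", "negative")) {
    obs_p <- observations[observations$polarity == pol, , drop = FALSE]
    cons[[pol]] <- align_runs(obs_p, ppm_tol = cfg$ppm_tolerance,
                              rt_tol = cfg$rt_align_tolerance_s)
  }
  fm <- build_matrix(cons$positive, cons$negative, samples)

  ann <- annotate_features(fm, library, cfg)
  comp <- strain_composition(
    fm, ann, presence_threshold = cfg$presence_threshold,
    confirmed_only = cfg$composition_confirmed_only)
  qc <- qc_internal_standards(fm, ppm_tol = cfg$ppm_tolerance)

  comp_out <- list()
  for (cmp in comparisons) {
    a <- cmp[1]; b <- cmp[2]
    key <- paste0(a, "_vs_", b)
    ds <- build_pairwise(fm, a, b)
    n_raw <- nrow(ds$features)
    ds <- filter_total_missing(ds)
    n_after_total <- nrow(ds$features)
    ds <- filter_presence(ds, cfg$presence_threshold)
    n_after_presence <- nrow(ds$features)
    ds <- impute_missing(ds, cfg$imputation_factor)
    ds <- cyclic_loess_normalize(ds, span = cfg$loess_span,
                                 iterations = cfg$loess_iterations,
                                 log_base = cfg$log_base)
    res <- differential_analysis(ds, cfg)
    comp_out[[key]] <- list(
      strain_a = a, strain_b = b,
      counts = c(raw = n_raw, after_total_missing = n_after_total,
                 after_presence = n_after_presence,
                 significant = sum(res$significant)),
      results = res,
      exclusives = ds$exclusives$presence,
      dataset = ds
    )
    if (!is.null(output_dir)) {
      dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
      volcano_export(res, file.path(output_dir,
                                    paste0("volcano_", key, ".tsv")),
                     annotations = ann)
      utils::write.table(
        ds$exclusives$presence,
        file.path(output_dir, paste0("exclusives_", key, ".tsv")),
        sep = "\t", row.names = FALSE, quote = FALSE)
    }
  }

  report <- structure(list(
    config = cfg,
    n_samples = nrow(samples),
    strains = strains,
    comparisons = comp_out,
    annotations = ann,
    composition = comp,
    standards_qc = qc,
    matrix = fm
  ), class = "run_report")

  if (!is.null(output_dir)) {
    dir.create(output_dir, showWarnings = FALSE, recursive = TRUE)
    write_feature_matrix(fm, file.path(output_dir, "feature_matrix.tsv"))
    utils::write.table(as.data.frame(ann),
                       file.path(output_dir, "annotations.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(as.data.frame(comp),
                       file.path(output_dir, "composition.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    utils::write.table(qc, file.path(output_dir, "standards_qc.tsv"),
                       sep = "\t", row.names = FALSE, quote = FALSE)
    jsonlite::write_json(report_summary(report),
                         file.path(output_dir, "run_report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

#' Machine-readable summary of a run report
#'
#' @param report A `run_report` from [run_pipeline()].
#' @return A plain list (JSON-serializable): config, per-comparison
#'   stage counts and significant totals, annotation counts by
#'   subclass, composition proportions, internal-standard QC.
#' @export
report_summary <- function(report) {
  conf <- report$annotations[report$annotations$confirmed, ,
                             drop = FALSE]
  by_class <- table(conf$subclass[!duplicated(
    paste(conf$name, conf$isomer_label))])
  list(
    config = unclass(report$config),
    n_samples = report$n_samples,
    strains = as.list(report$strains),
    comparisons = lapply(report$comparisons, function(cc) {
      list(strain_a = cc$strain_a, strain_b = cc$strain_b,
           counts = as.list(cc$counts),
           n_exclusives = nrow(cc$exclusives))
    }),
    annotation_counts = as.list(by_class),
    composition = split(
      stats::setNames(report$composition$proportion,
                      report$composition$subclass),
      report$composition$strain),
    standards_detected = sum(report$standards_qc$detected)
  )
}

#' Simulate a fixture set on disk
#'
#' Generates a ground truth and observations from a [sim_config()] and
#' writes them with [write_fixture()].
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory.
#' @return The ground truth, invisibly (observations attached as
#'   attribute `observations`).
#' @export
simulate_fixture <- function(cfg, dir) {
  truth <- generate_ground_truth(cfg)
  obs <- simulate_observations(truth, cfg)
  write_fixture(obs, truth, dir, cfg)
  attr(truth, "observations") <- obs
  invisible(truth)
}

#' @export
print.run_report <- function(x, ...) {
  cat("Strain-contrast lipidomics run\n")
  cat(sprintf("  samples: %d (%s)\n", x$n_samples,
              paste(x$strains, collapse = ", ")))
  cat(sprintf("  aligned features: %d\n", nrow(x$matrix$features)))
  for (key in names(x$comparisons)) {
    cc <- x$comparisons[[key]]
    cat(sprintf(
      "  %s vs %s: %d raw -> %d -> %d features; %d significant; %d exclusives\n",
      cc$strain_a, cc$strain_b, cc$counts["raw"],
      cc$counts["after_total_missing"], cc$counts["after_presence"],
      cc$counts["significant"], nrow(cc$exclusives)))
  }
  cat(sprintf("  confirmed annotations: %d rows; standards detected: %d/%d\n",
              sum(x$annotations$confirmed), sum(x$standards_qc$detected),
              nrow(x$standards_qc)))
  invisible(x)
}
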