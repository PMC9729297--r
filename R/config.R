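# Pipeline configuration: every tolerance and threshold used downstream.

#' Pipeline configuration
#'
#' Collects the tolerances and thresholds used across the pipeline.
#' Defaults follow the study design: 5 ppm mass gate for alignment and
#' annotation, 30 s cross-polarity coelution window, 15 s alignment RT
#' gate, 80% presence filter, imputation at 90% of the per-feature
#' minimum, p < 0.01 with fold change > 1.5 or < 0.667 for significance,
#' q < 0.05 reported alongside, cyclic loess with span 0.7 over 3
#' iterations.
#'
#' @param ppm_tolerance m/z gate (ppm) for alignment and annotation.
#' @param rt_tolerance_s Cross-polarity coelution window (seconds).
#' @param rt_align_tolerance_s Alignment retention-time gate (seconds).
#' @param presence_threshold Minimum fraction of replicates in which a
#'   feature must be observed in at least one strain of a pair.
#' @param imputation_factor Missing cells become this fraction of the
#'   per-feature minimum observed intensity.
#' @param p_threshold,q_threshold Significance gates; `p_threshold` is
#'   primary, `q_threshold` is reported alongside.
#' @param fc_upper,fc_lower Fold-change gates (strict inequalities).
#' @param loess_span,loess_iterations Cyclic loess parameters.
#' @param log_base Base of the log transform for normalization and
#'   statistics (2 by default).
#' @param welch Use Welch rather than pooled-variance statistics.
#' @param geometric_fc Use geometric rather than arithmetic group means
#'   for fold changes.
#' @param composition_confirmed_only Restrict composition summaries to
#'   cross-polarity-confirmed annotations.
#' @param random_seed Seed for any randomized step.
#' @return An object of class `pipeline_config` (a validated list).
#' @export
pipeline_config <- function(ppm_tolerance = 5,
                            rt_tolerance_s = 30,
                            rt_align_tolerance_s = 15,
                            presence_threshold = 0.8,
                            imputation_factor = 0.9,
                            p_threshold = 0.01,
                            q_threshold = 0.05,
                            fc_upper = 1.5,
                            fc_lower = 0.667,
                            loess_span = 0.7,
                            loess_iterations = 3,
                            log_base = 2,
                            welch = FALSE,
                            geometric_fc = FALSE,
                            composition_confirmed_only = TRUE,
                            random_seed = 1L) {
  cfg <- list(
    ppm_tolerance = ppm_tolerance,
    rt_tolerance_s = rt_tolerance_s,
    rt_align_tolerance_s = rt_align_tolerance_s,
    presence_threshold = presence_threshold,
    imputation_factor = imputation_factor,
    p_threshold = p_threshold,
    q_threshold = q_threshold,
    fc_upper = fc_upper,
    fc_lower = fc_lower,
    loess_span = loess_span,
    loess_iterations = loess_iterations,
    log_base = log_base,
    welch = isTRUE(welch),
    geometric_fc = isTRUE(geometric_fc),
    composition_confirmed_only = isTRUE(composition_confirmed_only),
    random_seed = as.integer(random_seed)
  )
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  stopifnot(
    cfg$ppm_tolerance > 0,
    cfg$rt_tolerance_s > 0,
    cfg$rt_align_tolerance_s > 0,
    cfg$presence_threshold > 0, cfg$presence_threshold <= 1,
    cfg$imputation_factor > 0,
    cfg$p_threshold > 0, cfg$q_threshold > 0,
    cfg$fc_lower < 1, cfg$fc_upper > 1,
    cfg$loess_span > 0, cfg$loess_span <= 1,
    cfg$loess_iterations >= 1,
    cfg$log_base > 1
  )
  invisible(cfg)
}

#' Read / write a pipeline configuration
#'
#' Flat YAML key-value file mirroring the [pipeline_config()] fields;
#' missing keys take their defaults.
#'
#' @param path File path.
#' @param cfg A `pipeline_config` object.
#' @return `read_pipeline_config()` returns a `pipeline_config`;
#'   `write_pipeline_config()` returns `path` invisibly.
#' @export
read_pipeline_config <- function(path) {
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipeline_config))
  unknown <- setdiff(names(vals), known)
  if (length(unknown)) {
    stop("unknown configuration key(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(pipeline_config, vals)
}

#' @rdname read_pipeline_config
#' @export
write_pipeline_config <- function(cfg, path) {
  yaml::write_yaml(unclass(cfg), path)
  invisible(path)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration:\n")
  for (k in names(x)) cat(sprintf("  %-27s %s\n", k, format(x[[k]])))
  invisible(x)
}
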