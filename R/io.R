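# Delimited-text I/O for feature observations and the lipid library.
# One row per detected peak in one run; RT is stored in seconds.

.OBS_COLUMNS <- c("sample_id", "strain", "polarity", "mz", "rt_seconds",
                  "intensity")

#' Read a per-sample feature observation table
#'
#' Reads comma- or tab-delimited text with one row per detected peak and
#' header columns `sample_id`, `strain`, `polarity`, `mz`, `rt_seconds`,
#' `intensity` (extra columns are ignored). The delimiter is sniffed
#' from the header line unless given.
#'
#' @param path File path.
#' @param sep Field delimiter; `NULL` (default) sniffs `","` vs `"\t"`.
#' @return A data.frame of observations with columns `sample_id`,
#'   `strain`, `polarity` (`"positive"`/`"negative"`), `mz` (Th),
#'   `rt` (seconds), `intensity`; row order preserved.
#' @export
read_feature_table <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character", comment.char = "")
  missing_cols <- setdiff(.OBS_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop("feature table is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  n <- nrow(raw)
  if (n == 0L) {
    return(empty_observations())
  }
  line <- seq_len(n) + 1L  # header is line 1
  pol <- tolower(trimws(raw$polarity))
  bad_pol <- !pol %in% c("positive", "negative")
  if (any(bad_pol)) {
    stop("invalid polarity '", raw$polarity[bad_pol][1], "' at line ",
         line[bad_pol][1], "; expected 'positive' or 'negative'",
         call. = FALSE)
  }
  num <- function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- is.na(v) & !is.na(raw[[col]])
    if (any(bad) || anyNA(raw[[col]])) {
      i <- which(bad | is.na(raw[[col]]))[1]
      stop("non-numeric ", col, " at line ", line[i], call. = FALSE)
    }
    v
  }
  mz <- num("mz"); rt <- num("rt_seconds"); intensity <- num("intensity")
  if (any(mz <= 0)) {
    stop("non-positive mz at line ", line[mz <= 0][1], call. = FALSE)
  }
  if (any(rt < 0)) {
    stop("negative rt_seconds at line ", line[rt < 0][1], call. = FALSE)
  }
  if (any(intensity < 0)) {
    stop("negative intensity at line ", line[intensity < 0][1],
         call. = FALSE)
  }
  data.frame(sample_id = raw$sample_id, strain = raw$strain,
             polarity = pol, mz = mz, rt = rt, intensity = intensity,
             stringsAsFactors = FALSE)
}

empty_observations <- function() {
  data.frame(sample_id = character(), strain = character(),
             polarity = character(), mz = numeric(), rt = numeric(),
             intensity = numeric(), stringsAsFactors = FALSE)
}

#' Write a feature observation table
#'
#' @param observations Data.frame as returned by [read_feature_table()].
#' @param path Output path; `.tsv` extension selects tab delimiting,
#'   anything else comma.
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(observations, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  out <- data.frame(sample_id = observations$sample_id,
                    strain = observations$strain,
                    polarity = observations$polarity,
                    mz = sprintf("%.6f", observations$mz),
                    rt_seconds = sprintf("%.3f", observations$rt),
                    intensity = sprintf("%.4f", observations$intensity),
                    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Read a lipid library
#'
#' Delimited text with columns `name`, `subclass`, `formula`,
#' `monoisotopic_mass` (the formula is optional when the mass is given,
#' and vice versa). When both are present the mass must agree with the
#' formula-derived mass within 1e-4 Da.
#'
#' @param path File path.
#' @param sep Field delimiter; sniffed when `NULL`.
#' @return A lipid library data.frame (see [default_lipid_library()]).
#' @export
read_lipid_library <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (is.null(sep)) {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
  }
  raw <- utils::read.table(path, header = TRUE, sep = sep,
                           stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("name", "subclass")
  missing_cols <- setdiff(need, names(raw))
  if (length(missing_cols)) {
    stop("lipid library is missing column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  formula <- if ("formula" %in% names(raw)) as.character(raw$formula)
             else rep(NA_character_, nrow(raw))
  formula[!nzchar(trimws(ifelse(is.na(formula), "", formula)))] <- NA
  mass <- if ("monoisotopic_mass" %in% names(raw))
            as.numeric(raw$monoisotopic_mass)
          else rep(NA_real_, nrow(raw))
  derived <- rep(NA_real_, nrow(raw))
  has_formula <- !is.na(formula)
  derived[has_formula] <- monoisotopic_mass(formula[has_formula])
  no_mass <- is.na(mass)
  mass[no_mass] <- derived[no_mass]
  if (anyNA(mass)) {
    stop("library row ", which(is.na(mass))[1],
         " has neither formula nor monoisotopic_mass", call. = FALSE)
  }
  both <- has_formula & !no_mass
  off <- both & abs(mass - derived) > 1e-4
  if (any(off)) {
    stop("library mass for '", raw$name[off][1],
         "' disagrees with its formula by ",
         signif(abs(mass - derived)[off][1], 3), " Da", call. = FALSE)
  }
  if (any(mass <= 0)) stop("non-positive library mass", call. = FALSE)
  is_standard <- if ("is_standard" %in% names(raw))
                   as.logical(raw$is_standard)
                 else rep(FALSE, nrow(raw))
  data.frame(name = as.character(raw$name),
             subclass = as.character(raw$subclass),
             formula = formula, monoisotopic_mass = mass,
             is_standard = is_standard, stringsAsFactors = FALSE)
}

#' Write a lipid library
#'
#' @param library Lipid library data.frame.
#' @param path Output path (`.tsv` for tabs, otherwise commas).
#' @return `path`, invisibly.
#' @export
write_lipid_library <- function(library, path) {
  sep <- if (grepl("\\.tsv$", path)) "\t" else ","
  out <- library
  out$monoisotopic_mass <- sprintf("%.6f", library$monoisotopic_mass)
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Write an aligned feature matrix as delimited text
#'
#' One row per consensus feature: `feature_id`, `polarity`, `mz`,
#' `rt_seconds`, then one intensity column per sample; empty cells mark
#' missing values.
#'
#' @param fm A `feature_matrix` (see [build_matrix()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_feature_matrix <- function(fm, path) {
  stopifnot(inherits(fm, "feature_matrix"))
  vals <- fm$values
  txt <- matrix("", nrow(vals), ncol(vals))
  obs <- !is.na(vals)
  txt[obs] <- sprintf("%.4f", vals[obs])
  out <- cbind(
    data.frame(feature_id = fm$features$feature_id,
               polarity = fm$features$polarity,
               mz = sprintf("%.6f", fm$features$mz),
               rt_seconds = sprintf("%.3f", fm$features$rt),
               stringsAsFactors = FALSE),
    as.data.frame(txt, stringsAsFactors = FALSE)
  )
  names(out)[-(1:4)] <- fm$samples$sample_id
  utils::write.table(out, path, sep = "\t", row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}
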