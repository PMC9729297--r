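# Exact-mass arithmetic shared by the simulator, annotation and QC stages.

# CODATA monoisotopic atomic masses (Da), most abundant isotope.
.MONOISOTOPIC <- c(
  H  = 1.0078250319,
  C  = 12.0,
  N  = 14.0030740052,
  O  = 15.9949146221,
  P  = 30.97376151,
  S  = 31.97207069,
  Na = 22.98976928,
  K  = 38.96370649,
  Cl = 34.96885268,
  F  = 18.99840316
)

# Mass shifts for singly charged ion forms. The charge carrier is the
# proton; the electron mass is folded into the 1.007276 Da constant.
# FA = formic acid, so [M+FA-H]- = M + HCOOH - H+ = M + 44.998203.
.ADDUCT_SHIFT <- c(
  "[M+H]+"    = +1.007276,
  "[M+NH4]+"  = +18.033823,
  "[M-H]-"    = -1.007276,
  "[M+FA-H]-" = +44.998203
)

.ADDUCT_POLARITY <- c(
  "[M+H]+"    = "positive",
  "[M+NH4]+"  = "positive",
  "[M-H]-"    = "negative",
  "[M+FA-H]-" = "negative"
)

#' Monoisotopic mass of an elemental formula
#'
#' Sums monoisotopic atomic masses over a Hill-style elemental formula
#' such as `"C16H32O2"`. Element symbols are one upper-case letter
#' optionally followed by one lower-case letter; a missing count means 1.
#'
#' @param formula Character vector of elemental formulas.
#' @return Numeric vector of neutral monoisotopic masses (Da).
#' @examples
#' monoisotopic_mass("C16H32O2") # palmitic acid, 256.2402
#' @export
monoisotopic_mass <- function(formula) {
  vapply(formula, function(f) {
    if (is.na(f) || !nzchar(f)) return(NA_real_)
    tokens <- gregexpr("[A-Z][a-z]?[0-9]*", f)[[1]]
    parts <- regmatches(f, list(tokens))[[1]]
    if (!length(parts) || sum(attr(tokens, "match.length")) != nchar(f)) {
      stop("malformed elemental formula: '", f, "'", call. = FALSE)
    }
    total <- 0
    for (p in parts) {
      sym <- sub("[0-9]*$", "", p)
      cnt <- sub("^[A-Za-z]+", "", p)
      n <- if (nzchar(cnt)) as.integer(cnt) else 1L
      if (!sym %in% names(.MONOISOTOPIC)) {
        stop("unknown element symbol '", sym, "' in formula '", f, "'",
             call. = FALSE)
      }
      total <- total + .MONOISOTOPIC[[sym]] * n
    }
    total
  }, numeric(1), USE.NAMES = FALSE)
}

#' m/z of a singly charged adduct ion
#'
#' @param neutral_mass Neutral monoisotopic mass (Da), positive.
#' @param adduct One of `"[M+H]+"`, `"[M+NH4]+"`, `"[M-H]-"`,
#'   `"[M+FA-H]-"` (FA = formic acid). Unicode minus signs are accepted.
#' @return m/z (Th) of the singly charged ion.
#' @examples
#' adduct_mz(256.2402, "[M-H]-") # 255.2330
#' @export
adduct_mz <- function(neutral_mass, adduct) {
  stopifnot(all(neutral_mass > 0))
  adduct <- normalize_adduct(adduct)
  bad <- !adduct %in% names(.ADDUCT_SHIFT)
  if (any(bad)) {
    stop("unsupported adduct '", adduct[bad][1], "'; supported: ",
         paste(names(.ADDUCT_SHIFT), collapse = ", "), call. = FALSE)
  }
  neutral_mass + unname(.ADDUCT_SHIFT[adduct])
}

# Map typographic minus/dash variants onto the ASCII rule table keys.
normalize_adduct <- function(adduct) {
  a <- gsub("−|–", "-", adduct)
  gsub(" ", "", a)
}

#' Relative mass error in parts per million
#'
#' @param observed,theoretical m/z values (Th), both positive.
#' @return `|observed - theoretical| / theoretical * 1e6`.
#' @export
ppm_error <- function(observed, theoretical) {
  stopifnot(all(observed > 0), all(theoretical > 0))
  abs(observed - theoretical) / theoretical * 1e6
}

#' Class-specific adduct rule table
#'
#' The ion forms required for annotation of each lipid subclass:
#' FFA `[M+NH4]+`/`[M-H]-`; PE `[M+H]+`/`[M-H]-`; PG `[M+NH4]+`/`[M-H]-`;
#' PC `[M+H]+`/`[M+FA-H]-`; MGDG and DGDG positive-only `[M+NH4]+`;
#' LPG negative-only `[M-H]-`. Dual-polarity subclasses require a
#' coeluting partner ion in the opposite polarity for confirmation;
#' single-polarity subclasses are confirmed on their one ion form.
#'
#' @return A data.frame with columns `subclass`, `positive_adduct`,
#'   `negative_adduct` (`NA` where the polarity has no required form).
#' @export
adduct_rules <- function() {
  data.frame(
    subclass        = c("FFA", "PE", "PG", "PC", "MGDG", "DGDG", "LPG"),
    positive_adduct = c("[M+NH4]+", "[M+H]+", "[M+NH4]+", "[M+H]+",
                        "[M+NH4]+", "[M+NH4]+", NA),
    negative_adduct = c("[M-H]-", "[M-H]-", "[M-H]-", "[M+FA-H]-",
                        NA, NA, "[M-H]-"),
    stringsAsFactors = FALSE
  )
}

# Required adduct of `subclass` in `polarity`, or NA if none.
rule_adduct <- function(subclass, polarity, rules = adduct_rules()) {
  col <- rep_len(ifelse(polarity == "positive",
                        "positive_adduct", "negative_adduct"),
                 length(subclass))
  idx <- match(subclass, rules$subclass)
  out <- rep(NA_character_, length(subclass))
  ok <- !is.na(idx)
  out[ok] <- ifelse(col[ok] == "positive_adduct",
                    rules$positive_adduct[idx[ok]],
                    rules$negative_adduct[idx[ok]])
  out
}
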