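# Bundled sum-composition lipid library.
#
# An editable stand-in annotation surface: free fatty acids C12-C24 with
# 0-3 double bonds, with and without a hydroxyl, plus sum-composition
# PE/PG/PC/MGDG/DGDG/LPG species (total acyl carbons 28-40) and the six
# spiked internal standards. Identities are sum compositions only
# (total carbons:double bonds); positional isomers are not resolved.

# Elemental formula of a sum-composition species. c = total acyl
# carbons, d = total double bonds. Backbones:
#   FFA  CcH(2c-2d)O2            (+O if hydroxylated)
#   PE   C(c+5)H(2c-2d+10)NO8P   diacyl-glycerophosphoethanolamine
#   PC   C(c+8)H(2c-2d+16)NO8P   diacyl-glycerophosphocholine
#   PG   C(c+6)H(2c-2d+11)O10P   diacyl-glycerophosphoglycerol
#   LPG  C(c+12)H(2c-2d+23)N2O11P  lysyl-PG (lysine ester on PG)
#   MGDG C(c+9)H(2c-2d+16)O10    monoglycosyl-diacylglycerol
#   DGDG C(c+15)H(2c-2d+26)O15   diglycosyl-diacylglycerol
sum_composition_formula <- function(subclass, carbons, double_bonds,
                                    hydroxyl = FALSE) {
  h <- 2 * carbons - 2 * double_bonds
  f <- switch(subclass,
    FFA  = sprintf("C%dH%dO%d", carbons, h, 2L + as.integer(hydroxyl)),
    PE   = sprintf("C%dH%dNO8P", carbons + 5L, h + 10L),
    PC   = sprintf("C%dH%dNO8P", carbons + 8L, h + 16L),
    PG   = sprintf("C%dH%dO10P", carbons + 6L, h + 11L),
    LPG  = sprintf("C%dH%dN2O11P", carbons + 12L, h + 23L),
    MGDG = sprintf("C%dH%dO10", carbons + 9L, h + 16L),
    DGDG = sprintf("C%dH%dO15", carbons + 15L, h + 26L),
    stop("no formula template for subclass '", subclass, "'",
         call. = FALSE)
  )
  f
}

#' Spiked internal standards
#'
#' The six internal standards carried through acquisition: LPC 13:0,
#' PC 19:0/19:0, PC 14:0/14:0, PS 12:0/12:0, PG 15:0/15:0 and
#' PE 17:0/17:0. They are monitored as a QC check (detected or not, and
#' at what mass error) only; they take no part in normalization or
#' composition summaries.
#'
#' @return A data.frame with columns `name`, `subclass`, `formula`,
#'   `monoisotopic_mass`, `qc_adduct` (the ion form used to look each
#'   standard up) and `is_standard = TRUE`.
#' @export
internal_standards <- function() {
  std <- data.frame(
    name = c("LPC 13:0", "PC 19:0/19:0", "PC 14:0/14:0",
             "PS 12:0/12:0", "PG 15:0/15:0", "PE 17:0/17:0"),
    subclass = c("other", "PC", "PC", "other", "PG", "PE"),
    formula = c("C21H44NO7P", "C46H92NO8P", "C36H72NO8P",
                "C30H58NO10P", "C36H71O10P", "C39H78NO8P"),
    qc_adduct = c("[M+H]+", "[M+H]+", "[M+H]+",
                  "[M-H]-", "[M-H]-", "[M+H]+"),
    stringsAsFactors = FALSE
  )
  std$monoisotopic_mass <- monoisotopic_mass(std$formula)
  std$is_standard <- TRUE
  std[, c("name", "subclass", "formula", "monoisotopic_mass",
          "qc_adduct", "is_standard")]
}

#' Bundled sum-composition lipid library
#'
#' @param ffa_carbons,ffa_double_bonds Carbon and double-bond ranges for
#'   the free fatty acid block (hydroxylated variants are included).
#' @param pl_carbons,pl_double_bonds Ranges for the
#'   PE/PG/PC/MGDG/DGDG/LPG sum-composition block.
#' @param standards Include the six internal standards (flagged
#'   `is_standard`).
#' @return A data.frame with columns `name`, `subclass`, `formula`,
#'   `monoisotopic_mass`, `is_standard`.
#' @examples
#' lib <- default_lipid_library()
#' subset(lib, name == "FFA 16:0")
#' @export
default_lipid_library <- function(ffa_carbons = 12:24,
                                  ffa_double_bonds = 0:3,
                                  pl_carbons = 28:40,
                                  pl_double_bonds = 0:3,
                                  standards = TRUE) {
  ffa <- expand.grid(carbons = ffa_carbons, d = ffa_double_bonds,
                     oh = c(FALSE, TRUE))
  ffa <- ffa[ffa$d < ffa$carbons / 2, ]
  ffa_rec <- data.frame(
    name = sprintf("FFA %d:%d%s", ffa$carbons, ffa$d,
                   ifelse(ffa$oh, ";OH", "")),
    subclass = "FFA",
    formula = mapply(sum_composition_formula, "FFA", ffa$carbons, ffa$d,
                     ffa$oh),
    stringsAsFactors = FALSE
  )
  pl <- expand.grid(carbons = pl_carbons, d = pl_double_bonds,
                    subclass = c("PE", "PG", "PC", "MGDG", "DGDG", "LPG"),
                    stringsAsFactors = FALSE)
  pl_rec <- data.frame(
    name = sprintf("%s %d:%d", pl$subclass, pl$carbons, pl$d),
    subclass = pl$subclass,
    formula = mapply(sum_composition_formula, pl$subclass, pl$carbons,
                     pl$d),
    stringsAsFactors = FALSE
  )
  lib <- rbind(ffa_rec, pl_rec)
  lib$monoisotopic_mass <- monoisotopic_mass(lib$formula)
  lib$is_standard <- FALSE
  if (standards) {
    std <- internal_standards()
    lib <- rbind(lib, std[, names(lib)])
  }
  rownames(lib) <- NULL
  lib
}
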