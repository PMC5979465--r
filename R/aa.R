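#' Amino acid alphabets and physicochemical groupings
#'
#' Constants used across the feature and conservation code. `AA20` is the
#' canonical 20-letter alphabet in the fixed order used by every
#' position-specific score and one-hot block in the package; changing this
#' order would silently reorder 1000+ feature columns, so it is frozen here.
#'
#' @format `AA20` is a character vector of the 20 one-letter codes.
#' @name aa-constants
NULL

#' @rdname aa-constants
#' @export
AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
          "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

# Six physicochemical substitution-type groups used by the 6x6 one-hot block.
AA_GROUPS6 <- list(
  hydrophobic = c("V", "I", "L", "F", "M", "W", "Y", "C"),
  negative    = c("D", "E"),
  positive    = c("R", "K", "H"),
  conformational = c("G", "P"),
  polar       = c("N", "Q", "S"),
  other       = c("A", "T")
)

# Residue classes for the five neighbourhood composition counts. Note that
# histidine sits with the polar-uncharged residues here, while the 6x6
# substitution grouping above places it with the positively charged ones;
# the two schemes serve different feature families and are kept distinct.
AA_CLASSES5 <- list(
  nonpolar = c("A", "V", "L", "I", "P", "F", "M", "W", "G", "C"),
  polar    = c("S", "T", "Y", "N", "Q", "H"),
  positive = c("K", "R"),
  negative = c("D", "E")
)
AA_CLASSES5$charged <- c(AA_CLASSES5$positive, AA_CLASSES5$negative)

aa_group6 <- function(aa) {
  hit <- vapply(AA_GROUPS6, function(g) aa %in% g, logical(1))
  names(AA_GROUPS6)[which(hit)[1]]
}

check_aa <- function(aa, what = "residue") {
  bad <- !(aa %in% AA20)
  if (any(bad)) {
    stop(sprintf("non-canonical %s code: %s", what,
                 paste(unique(aa[bad]), collapse = ", ")), call. = FALSE)
  }
  invisible(aa)
}

# kJ/mol -> kcal/mol divisor (thermochemical calorie)
KJ_PER_KCAL <- 4.184
# temperatures above this are taken to be Kelvin readings
KELVIN_SUSPECT_C <- 150
KELVIN_OFFSET <- 273.15

#' @rdname aa-constants
#' @format `STABILITY_CLASSES` is the fixed order of the three outcome
#'   classes.
#' @export
STABILITY_CLASSES <- c("increase", "no_effect", "decrease")
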