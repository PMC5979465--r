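#' Packaged benchmark evaluation counts
#'
#' One-vs-rest confusion counts (TP, FN, FP per class) from published
#' evaluations of three-class stability predictors, shipped as plain TSV
#' under `inst/extdata`:
#' \describe{
#'   \item{`blind`}{the retrained two-layer predictor on its 165-variant
#'     blind test set of homology-unrelated proteins.}
#'   \item{`cv_mean`}{mean per-fold counts of the same predictor over
#'     five-fold cross-validation (non-integral).}
#'   \item{`imutant`}{a comparison tool on the 40-variant subset never
#'     seen by any of the compared tools.}
#' }
#' The counts reconstruct, via [confusion_from_ovr()], confusion matrices
#' whose diagonal and margins are exact, which is all the correct
#' prediction ratio and class-size normalization depend on.
#'
#' @param which one of `"blind"`, `"cv_mean"`, `"imutant"`.
#' @return a `confusion_matrix` over the three stability classes.
#' @export
benchmark_confusion <- function(which = c("blind", "cv_mean", "imutant")) {
  which <- match.arg(which)
  path <- system.file("extdata",
                      paste0("benchmark_", which, "_counts.tsv"),
                      package = "protstab", mustWork = TRUE)
  df <- read.delim(path)
  tp <- setNames(df$tp, df$class)
  fn <- setNames(df$fn, df$class)
  fp <- setNames(df$fp, df$class)
  confusion_from_ovr(tp, fn, fp)
}
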