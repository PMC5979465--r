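#' Confusion matrix from labels
#'
#' Rows are true classes, columns predicted classes. Counts may be
#' non-integral (e.g. after class-size normalization or per-fold
#' averaging).
#'
#' @param truth,pred vectors of class labels.
#' @param classes class order; defaults to the union of observed levels.
#' @return a K x K matrix of class `confusion_matrix`.
#' @export
confusion_matrix <- function(truth, pred, classes = NULL) {
  truth <- as.character(truth); pred <- as.character(pred)
  if (is.null(classes)) classes <- sort(unique(c(truth, pred)))
  z <- table(factor(truth, levels = classes),
             factor(pred, levels = classes))
  z <- unclass(as.matrix(z))
  dimnames(z) <- list(true = classes, predicted = classes)
  as_confusion(z)
}

#' Coerce a square count matrix to a confusion matrix
#'
#' @param z square numeric matrix, rows = true classes.
#' @return object of class `confusion_matrix`.
#' @export
as_confusion <- function(z) {
  z <- as.matrix(z)
  stopifnot(nrow(z) == ncol(z), all(z >= 0), sum(z) > 0)
  class(z) <- c("confusion_matrix", class(z))
  z
}

#' One-vs-rest binary counts for a class
#'
#' @param m a `confusion_matrix`.
#' @param class class name or index.
#' @return named vector `(TP, FN, FP, TN)`; always sums to `sum(m)`.
#' @export
binary_counts <- function(m, class) {
  i <- if (is.character(class)) match(class, rownames(m)) else class
  stopifnot(!is.na(i))
  tp <- m[i, i]
  fn <- sum(m[i, ]) - tp
  fp <- sum(m[, i]) - tp
  tn <- sum(m) - tp - fn - fp
  c(TP = tp, FN = fn, FP = fp, TN = tn)
}

#' Binary classification metrics
#'
#' Accuracy, positive and negative predictive value, sensitivity (TPR),
#' specificity (TNR) and the Matthews correlation coefficient from TP,
#' TN, FP, FN counts. A metric whose denominator is zero is reported as
#' `NA` (undefined and flagged), never silently as 0.
#'
#' @param counts named vector with `TP`, `FN`, `FP`, `TN` (reals
#'   allowed).
#' @return named numeric vector `(accuracy, ppv, npv, tpr, tnr, mcc)`
#'   with attribute `undefined` naming the flagged metrics.
#' @export
binary_metrics <- function(counts) {
  tp <- counts[["TP"]]; tn <- counts[["TN"]]
  fp <- counts[["FP"]]; fn <- counts[["FN"]]
  safe <- function(num, den) if (den > 0) num / den else NA_real_
  mcc_den <- sqrt(tp + fn) * sqrt(tp + fp) * sqrt(tn + fn) * sqrt(tn + fp)
  out <- c(accuracy = safe(tp + tn, tp + tn + fp + fn),
           ppv = safe(tp, tp + fp),
           npv = safe(tn, tn + fn),
           tpr = safe(tp, tp + fn),
           tnr = safe(tn, tn + fp),
           mcc = if (mcc_den > 0) (tp * tn - fp * fn) / mcc_den
                 else NA_real_)
  attr(out, "undefined") <- names(out)[is.na(out)]
  out
}

#' Correct prediction ratio
#'
#' The multi-class analogue of accuracy: the trace of the confusion
#' matrix over the total count.
#'
#' @param m a `confusion_matrix`.
#' @return value in `[0, 1]`.
#' @export
cpr <- function(m) {
  sum(diag(m)) / sum(m)
}

#' Generalized squared correlation
#'
#' A chi-square-based multi-class association measure in `[0, 1]`:
#' `sum_ij (z_ij - e_ij)^2 / (e_ij * N * (K - 1))` with expected counts
#' `e_ij = x_i * y_j / N` from the matrix's own margins. Equals the
#' squared Matthews correlation coefficient on 2x2 matrices. Undefined
#' (flagged `NA`) when any row or column margin is zero, as happens when
#' a tool never predicts one of the classes.
#'
#' @param m a `confusion_matrix`.
#' @return value in `[0, 1]`, or `NA` with attribute `undefined`.
#' @export
gc2 <- function(m) {
  rs <- rowSums(m); cs <- colSums(m); n <- sum(m)
  if (any(rs == 0) || any(cs == 0)) {
    out <- NA_real_
    attr(out, "undefined") <- TRUE
    return(out)
  }
  e <- outer(rs, cs) / n
  k <- nrow(m)
  sum((m - e)^2 / e) / (n * (k - 1))
}

#' Normalize confusion-matrix rows to a reference class size
#'
#' With classes of very different sizes, raw counts make the per-class
#' measures incomparable. Each true-class row is rescaled by
#' `rowsum(reference) / rowsum(class)` so every true class has the same
#' total as the reference class; within-row proportions are preserved
#' exactly, and all column-derived quantities are recomputed from the
#' scaled matrix downstream.
#'
#' @param m a `confusion_matrix`.
#' @param reference_class name or index of the reference class.
#' @return the rescaled `confusion_matrix`.
#' @export
normalize_to_reference <- function(m, reference_class) {
  i <- if (is.character(reference_class)) {
    match(reference_class, rownames(m))
  } else reference_class
  stopifnot(!is.na(i))
  rs <- rowSums(m)
  if (any(rs == 0)) stop("zero row in confusion matrix", call. = FALSE)
  scaled <- m * (rs[i] / rs)
  as_confusion(unclass(scaled))
}

#' Average a list of per-fold matrices after normalizing each
#'
#' The per-fold normalization mode: each fold's matrix is scaled to its
#' own reference class size, then the element-wise mean is taken.
#'
#' @param ms list of `confusion_matrix` objects with identical classes.
#' @param reference_class reference class for the scaling.
#' @return mean normalized `confusion_matrix`.
#' @export
normalize_folds <- function(ms, reference_class) {
  scaled <- lapply(ms, normalize_to_reference, reference_class)
  as_confusion(Reduce(`+`, lapply(scaled, unclass)) / length(scaled))
}

#' Reconstruct a 3x3 confusion matrix from one-vs-rest counts
#'
#' Published evaluations often print only the per-class TP/FN/FP counts.
#' The diagonal and both margins of the underlying K x K matrix are fully
#' determined by them; the off-diagonal split is not, so it is filled by
#' iterative proportional fitting of the off-diagonal cells to the row
#' (FN) and column (FP) remainders. Every quantity that depends only on
#' the diagonal and the margins (CPR, normalized CPR, all one-vs-rest
#' measures) is exact.
#'
#' @param tp,fn,fp named numeric vectors over the classes (identical
#'   names, `sum(fn) == sum(fp)`).
#' @return a `confusion_matrix`.
#' @export
confusion_from_ovr <- function(tp, fn, fp) {
  classes <- names(tp)
  stopifnot(!is.null(classes), identical(names(fn), classes),
            identical(names(fp), classes))
  if (abs(sum(fn) - sum(fp)) > 1e-8) {
    stop("inconsistent one-vs-rest counts: sum(FN) != sum(FP)",
         call. = FALSE)
  }
  k <- length(classes)
  z <- matrix(0, k, k, dimnames = list(true = classes, predicted = classes))
  diag(z) <- tp
  off <- outer(fn, fp) / max(sum(fn), 1e-12)
  diag(off) <- 0
  for (it in seq_len(200)) {
    rs <- rowSums(off)
    scale_r <- ifelse(rs > 0, fn / rs, 1)
    off <- off * scale_r
    cs <- colSums(off)
    scale_c <- ifelse(cs > 0, fp / cs, 1)
    off <- sweep(off, 2, scale_c, `*`)
  }
  z <- z + off
  as_confusion(z)
}

#' Round half away from zero
#'
#' Display rounding used in the report tables (standard half-up, unlike
#' base R's round-half-to-even).
#'
#' @param x numeric.
#' @param digits decimal places.
#' @return rounded values.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Comprehensive evaluation report
#'
#' Per-class one-vs-rest accuracy, PPV, NPV, sensitivity and specificity
#' (plus MCC for binary problems), CPR and the generalized squared
#' correlation, each computed on the raw matrix and, for multi-class
#' problems, on the class-size-normalized matrix. Normalized counts are
#' displayed rounded to one decimal, but all metrics are computed from
#' the unrounded values.
#'
#' @param m a `confusion_matrix`.
#' @param reference_class reference class for normalization (ignored for
#'   binary input).
#' @return object of class `metrics_report`: list with `raw` and
#'   `normalized` sub-lists (`per_class` data.frame, `cpr`, `gc2`,
#'   `matrix`).
#' @export
full_report <- function(m, reference_class = "no_effect") {
  one <- function(mat) {
    per <- do.call(rbind, lapply(rownames(mat), function(cl) {
      bm <- binary_metrics(binary_counts(mat, cl))
      data.frame(class = cl, t(as.numeric(bm)), stringsAsFactors = FALSE)
    }))
    names(per) <- c("class", "accuracy", "ppv", "npv", "tpr", "tnr", "mcc")
    list(per_class = per, cpr = cpr(mat), gc2 = as.numeric(gc2(mat)),
         matrix = mat)
  }
  out <- list(raw = one(m))
  if (nrow(m) > 2) {
    out$normalized <- one(normalize_to_reference(m, reference_class))
  } else {
    out$normalized <- NULL
  }
  class(out) <- "metrics_report"
  out
}

#' @export
print.metrics_report <- function(x, ...) {
  cat("Raw confusion matrix:\n")
  print(round_half_up(unclass(x$raw$matrix), 1))
  cat(sprintf("CPR %.3f  GC2 %s\n", x$raw$cpr,
              ifelse(is.na(x$raw$gc2), "NA", sprintf("%.3f", x$raw$gc2))))
  print(transform(x$raw$per_class,
                  accuracy = round_half_up(accuracy, 3),
                  ppv = round_half_up(ppv, 3), npv = round_half_up(npv, 3),
                  tpr = round_half_up(tpr, 3), tnr = round_half_up(tnr, 3),
                  mcc = round_half_up(mcc, 3)))
  if (!is.null(x$normalized)) {
    cat("\nNormalized to reference class size:\n")
    print(round_half_up(unclass(x$normalized$matrix), 1))
    cat(sprintf("CPR %.3f  GC2 %s\n", x$normalized$cpr,
                ifelse(is.na(x$normalized$gc2), "NA",
                       sprintf("%.3f", x$normalized$gc2))))
  }
  invisible(x)
}

#' Read / write a confusion matrix as TSV with class-name headers
#'
#' @param path TSV path; rows = true classes, header = predicted classes,
#'   first column = class names.
#' @return a `confusion_matrix`.
#' @export
read_confusion <- function(path) {
  df <- read.delim(path, check.names = FALSE)
  z <- as.matrix(df[, -1, drop = FALSE])
  dimnames(z) <- list(true = df[[1]], predicted = colnames(z))
  as_confusion(z)
}

#' @rdname read_confusion
#' @param m a `confusion_matrix` to write.
#' @export
write_confusion <- function(m, path) {
  df <- data.frame(class = rownames(m), unclass(m), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
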