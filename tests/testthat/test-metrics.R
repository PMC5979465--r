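test_that("binary metrics reproduce the published one-vs-rest example", {
  # decrease one-vs-rest of a comparison tool on the 40-variant set
  bm <- binary_metrics(c(TP = 22, TN = 3, FP = 11, FN = 4))
  expect_equal(bm[["tpr"]], 22 / 26)
  expect_equal(round_half_up(bm[["tpr"]], 2), 0.85)
  expect_equal(bm[["ppv"]], 22 / 33)
  expect_equal(round_half_up(bm[["ppv"]], 2), 0.67)
  # perfect prediction: every metric is 1
  perfect <- binary_metrics(c(TP = 10, TN = 5, FP = 0, FN = 0))
  expect_equal(as.numeric(perfect), rep(1, 6), tolerance = 1e-12)
  # no association: MCC 0, accuracy 0.5
  none <- binary_metrics(c(TP = 25, TN = 25, FP = 25, FN = 25))
  expect_equal(none[["mcc"]], 0)
  expect_equal(none[["accuracy"]], 0.5)
})

test_that("undefined metrics are flagged NA, never reported as zero", {
  bm <- binary_metrics(c(TP = 0, TN = 10, FP = 0, FN = 5))
  expect_true(is.na(bm[["ppv"]]))
  expect_true("ppv" %in% attr(bm, "undefined"))
  expect_false(is.na(bm[["npv"]]))
})

test_that("CPR is the diagonal fraction, matching the published tables", {
  expect_equal(cpr(as_confusion(diag(c(5, 3, 9)))), 1)
  expect_equal(cpr(benchmark_confusion("imutant")), 0.60, tolerance = 1e-9)
  expect_equal(round_half_up(cpr(benchmark_confusion("blind")), 3), 0.552)
  expect_equal(round_half_up(cpr(benchmark_confusion("cv_mean")), 3), 0.520)
})

test_that("GC2 agrees with an independent chi-square oracle", {
  z <- matrix(c(8, 1, 1, 2, 6, 2, 1, 1, 8), 3, 3, byrow = TRUE,
              dimnames = list(c("i", "n", "d"), c("i", "n", "d")))
  m <- as_confusion(z)
  oracle <- suppressWarnings(
    chisq.test(z, correct = FALSE)$statistic)
  expect_equal(as.numeric(gc2(m)),
               as.numeric(oracle) / (sum(z) * (3 - 1)), tolerance = 1e-12)
  # perfect balanced prediction: 1; exact independence: 0
  expect_equal(as.numeric(gc2(as_confusion(diag(c(7, 7, 7))))), 1)
  indep <- as_confusion(outer(c(10, 20, 30), c(1, 2, 3)) / 6)
  expect_equal(as.numeric(gc2(indep)), 0, tolerance = 1e-12)
})

test_that("GC2 stays in [0,1], equals MCC^2 on 2x2, and is permutation invariant", {
  set.seed(93)
  for (i in 1:25) {
    z <- matrix(rpois(4, 20) + 1, 2, 2,
                dimnames = list(c("a", "b"), c("a", "b")))
    m <- as_confusion(z)
    g <- as.numeric(gc2(m))
    expect_gte(g, 0); expect_lte(g, 1)
    mcc <- binary_metrics(c(TP = z[1, 1], FN = z[1, 2], FP = z[2, 1],
                            TN = z[2, 2]))[["mcc"]]
    expect_equal(g, mcc^2, tolerance = 1e-10)
  }
  z3 <- matrix(rpois(9, 15) + 1, 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  p <- c(3, 1, 2)
  expect_equal(as.numeric(gc2(as_confusion(z3))),
               as.numeric(gc2(as_confusion(z3[p, p]))), tolerance = 1e-12)
  # zero margin: undefined and flagged
  z0 <- matrix(c(5, 0, 3, 0, 0, 0, 2, 0, 4), 3, 3,
               dimnames = list(letters[1:3], letters[1:3]))
  expect_true(is.na(gc2(as_confusion(z0))))
})

test_that("class-size normalization reproduces the published scaled counts", {
  m <- benchmark_confusion("blind")
  nm <- normalize_to_reference(m, "no_effect")
  # decrease row (92 cases) scaled to the 50-case reference: TP 66 -> 35.9
  expect_equal(round_half_up(nm["decrease", "decrease"], 1), 35.9)
  # increase FN 20 -> 43.5
  expect_equal(round_half_up(sum(nm["increase", ]) -
                               nm["increase", "increase"], 1), 43.5)
  # reference row unchanged
  expect_equal(nm["no_effect", ], m["no_effect", ])
  # normalized CPR matches the published 0.429
  expect_equal(round_half_up(cpr(nm), 3), 0.429)
})

test_that("normalization preserves row proportions and equalizes row sums exactly", {
  set.seed(97)
  z <- matrix(runif(9, 1, 50), 3, 3,
              dimnames = list(letters[1:3], letters[1:3]))
  m <- as_confusion(z)
  nm <- normalize_to_reference(m, "b")
  expect_equal(as.numeric(rowSums(nm)), rep(sum(m["b", ]), 3),
               tolerance = 1e-12)
  for (i in 1:3) {
    expect_equal(as.numeric(nm[i, ] / sum(nm[i, ])),
                 as.numeric(m[i, ] / sum(m[i, ])), tolerance = 1e-12)
  }
  expect_error(normalize_to_reference(
    as_confusion(matrix(c(1, 0, 0, 0, 0, 0, 0, 0, 2), 3, 3)), 1),
    "zero row")
})

test_that("one-vs-rest collapse conserves the total count", {
  z <- benchmark_confusion("blind")
  for (cl in rownames(z)) {
    expect_equal(sum(binary_counts(z, cl)), sum(z))
  }
})

test_that("matrices rebuilt from one-vs-rest counts have exact diagonal and margins", {
  m <- benchmark_confusion("blind")
  expect_equal(as.numeric(diag(m)), c(3, 66, 22))
  expect_equal(as.numeric(rowSums(m)), c(23, 92, 50), tolerance = 1e-8)
  expect_equal(as.numeric(colSums(m)), c(19, 102, 44), tolerance = 1e-8)
  expect_error(confusion_from_ovr(c(a = 1, b = 1), c(a = 2, b = 0),
                                  c(a = 0, b = 1)),
               "inconsistent")
})

test_that("the full report reproduces the blind-test evaluation end-to-end", {
  rep <- full_report(benchmark_confusion("blind"), "no_effect")
  expect_equal(round_half_up(rep$raw$cpr, 3), 0.552)
  expect_equal(round_half_up(rep$normalized$cpr, 3), 0.429)
  # sensitivities are row-scaling invariant
  raw_tpr <- rep$raw$per_class$tpr
  expect_equal(round_half_up(raw_tpr, 3), c(0.130, 0.717, 0.440))
  expect_equal(rep$normalized$per_class$tpr, raw_tpr, tolerance = 1e-10)
  # binary input: MCC present, no normalization block
  b <- as_confusion(matrix(c(20, 5, 3, 22), 2, 2,
                           dimnames = list(c("x", "y"), c("x", "y"))))
  rep2 <- full_report(b)
  expect_false(is.na(rep2$raw$per_class$mcc[1]))
  expect_null(rep2$normalized)
  # class relabeling permutes the report consistently
  m <- benchmark_confusion("blind")
  p <- c(2, 3, 1)
  rep3 <- full_report(as_confusion(unclass(m)[p, p]), "no_effect")
  expect_equal(rep3$raw$cpr, rep$raw$cpr)
  expect_equal(rep3$normalized$cpr, rep$normalized$cpr, tolerance = 1e-10)
})

test_that("per-fold normalization averages fold matrices on a common scale", {
  z1 <- as_confusion(matrix(c(8, 2, 2, 1, 4, 1, 3, 3, 14), 3, 3,
                            byrow = TRUE,
                            dimnames = list(letters[1:3], letters[1:3])))
  z2 <- as_confusion(unclass(z1)[c(2, 1, 3), c(2, 1, 3)])
  dimnames(z2) <- dimnames(z1)
  nf <- normalize_folds(list(z1, z2), "b")
  # every true class carries equal weight in the averaged matrix
  expect_equal(max(rowSums(nf)) - min(rowSums(nf)), 0, tolerance = 1e-12)
  # averaging identical folds is the identity
  nf2 <- normalize_folds(list(z1, z1), "b")
  expect_equal(unclass(nf2), unclass(normalize_to_reference(z1, "b")),
               tolerance = 1e-12)
})

test_that("confusion matrices round-trip through TSV", {
  m <- benchmark_confusion("imutant")
  path <- tempfile(fileext = ".tsv")
  write_confusion(m, path)
  back <- read_confusion(path)
  expect_equal(unclass(back), unclass(m), tolerance = 1e-6)
})
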