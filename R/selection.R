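rf_fit <- function(x, y, ntree = 300) {
  if (nlevels(droplevels(factor(y))) < 2) {
    stop("degenerate single-class training set", call. = FALSE)
  }
  randomForest::randomForest(x = as.data.frame(x), y = factor(y),
                             ntree = ntree)
}

rf_error <- function(fit, x_test, y_test) {
  pred <- predict(fit, as.data.frame(x_test))
  mean(as.character(pred) != as.character(y_test))
}

#' Backward elimination to a fixed feature count
#'
#' Iteratively trains a random forest on the current feature set, removes
#' the feature with the smallest impurity-based importance, and records
#' the test error of each step, until `target_size` features remain.
#' Both the terminal subset and the best-scoring intermediate subset
#' along the elimination path are returned; `keep` selects which one the
#' `features` element reports (terminal by default, for determinism under
#' ties).
#'
#' @param x_train,y_train training features (matrix/data.frame) and
#'   labels.
#' @param x_test,y_test held-out part of the fold for the error path.
#' @param target_size number of features to keep.
#' @param ntree trees per forest.
#' @param seed RNG seed.
#' @param keep `"terminal"` or `"best"` (lowest error along the path).
#' @return list with `features`, `terminal`, `best`, and `trace`
#'   (data.frame `iteration`, `removed`, `n_features`, `test_error`).
#' @export
backward_eliminate <- function(x_train, y_train, x_test, y_test,
                               target_size = 8, ntree = 300, seed = 1,
                               keep = c("terminal", "best")) {
  keep <- match.arg(keep)
  features <- colnames(x_train)
  stopifnot(length(features) >= target_size)
  set.seed(seed)
  trace <- data.frame(iteration = integer(), removed = character(),
                      n_features = integer(), test_error = numeric(),
                      stringsAsFactors = FALSE)
  path <- list()
  it <- 0
  while (length(features) > target_size) {
    fit <- rf_fit(x_train[, features, drop = FALSE], y_train, ntree)
    err <- rf_error(fit, x_test[, features, drop = FALSE], y_test)
    imp <- randomForest::importance(fit)[, 1]
    worst <- names(imp)[order(imp, seq_along(imp))][1]
    it <- it + 1
    trace <- rbind(trace, data.frame(iteration = it, removed = worst,
                                     n_features = length(features),
                                     test_error = err,
                                     stringsAsFactors = FALSE))
    path[[it]] <- features
    features <- setdiff(features, worst)
  }
  # error of the terminal subset itself
  fit <- rf_fit(x_train[, features, drop = FALSE], y_train, ntree)
  terminal_err <- rf_error(fit, x_test[, features, drop = FALSE], y_test)
  best <- features
  if (nrow(trace) > 0) {
    errs <- c(trace$test_error, terminal_err)
    best_idx <- which.min(errs)
    best <- if (best_idx > length(path)) features else path[[best_idx]]
  }
  list(features = if (keep == "terminal") features else best,
       terminal = features, best = best, trace = trace)
}

#' Merge per-fold feature subsets
#'
#' Order-stable union with duplicates eliminated (first occurrence wins).
#'
#' @param subsets list of feature-name character vectors.
#' @return character vector of unique candidate features.
#' @export
merge_subsets <- function(subsets) {
  unique(unlist(subsets, use.names = FALSE))
}

#' Cross-validated error function over feature subsets
#'
#' Returns a closure evaluating the mean misclassification rate of a
#' random forest over the supplied folds, restricted to a feature subset.
#' Seeded per call so identical subsets always score identically.
#'
#' @param x feature matrix; `y` labels.
#' @param folds list of `list(train = idx, test = idx)` pairs.
#' @param ntree trees per forest.
#' @param seed RNG seed.
#' @return `function(features) -> mean CV error`.
#' @export
cv_error_fn <- function(x, y, folds, ntree = 300, seed = 1) {
  function(features) {
    set.seed(seed)
    errs <- vapply(folds, function(f) {
      fit <- rf_fit(x[f$train, features, drop = FALSE], y[f$train], ntree)
      rf_error(fit, x[f$test, features, drop = FALSE], y[f$test])
    }, numeric(1))
    mean(errs)
  }
}

#' Greedy forward feature selection
#'
#' Starts from the empty set; each round evaluates every unchosen
#' candidate added to the chosen set and accepts the one with the lowest
#' error, but only if it strictly reduces the error of the previous
#' round; stops at the first round with no strict reduction. Ties are
#' broken by candidate order.
#'
#' @param candidates ordered character vector of candidate features.
#' @param eval_fn function mapping a feature-name vector to an error
#'   rate; typically [cv_error_fn()].
#' @return list with `features` (ordered as accepted) and `trace`
#'   (data.frame `round`, `added`, `error`).
#' @export
forward_select <- function(candidates, eval_fn) {
  stopifnot(length(candidates) >= 1)
  chosen <- character(0)
  best_err <- Inf
  trace <- data.frame(round = integer(), added = character(),
                      error = numeric(), stringsAsFactors = FALSE)
  round_i <- 0
  repeat {
    remaining <- setdiff(candidates, chosen)
    if (!length(remaining)) break
    errs <- vapply(remaining, function(f) eval_fn(c(chosen, f)), numeric(1))
    pick <- which(errs == min(errs))[1]
    if (errs[pick] >= best_err) break
    round_i <- round_i + 1
    chosen <- c(chosen, remaining[pick])
    best_err <- errs[pick]
    trace <- rbind(trace, data.frame(round = round_i,
                                     added = remaining[pick],
                                     error = best_err,
                                     stringsAsFactors = FALSE))
  }
  list(features = chosen, trace = trace)
}

#' Two-step feature selection over a cross-validation plan
#'
#' Step one runs backward elimination independently in each fold (train
#' on four partitions, score on the fifth) down to `target_size`
#' features; the per-fold subsets are merged without duplicates. Step two
#' runs greedy forward selection over the merged candidates, scored by
#' mean error over the same folds.
#'
#' @param x feature matrix; `y` labels.
#' @param folds list of `list(train, test)` index pairs.
#' @param target_size per-fold subset size.
#' @param ntree trees per forest.
#' @param seed RNG seed.
#' @param keep passed to [backward_eliminate()].
#' @return list with `features`, `candidates`, `fold_subsets`,
#'   `forward_trace`.
#' @export
select_features <- function(x, y, folds, target_size = 8, ntree = 300,
                            seed = 1, keep = "terminal") {
  fold_subsets <- lapply(seq_along(folds), function(i) {
    f <- folds[[i]]
    backward_eliminate(x[f$train, , drop = FALSE], y[f$train],
                       x[f$test, , drop = FALSE], y[f$test],
                       target_size = target_size, ntree = ntree,
                       seed = seed + i, keep = keep)$features
  })
  candidates <- merge_subsets(fold_subsets)
  fwd <- forward_select(candidates, cv_error_fn(x, y, folds, ntree, seed))
  list(features = fwd$features, candidates = candidates,
       fold_subsets = fold_subsets, forward_trace = fwd$trace)
}

#' Build fold index pairs from a CV plan
#'
#' @param plan a `cv_plan`.
#' @param protein_ids protein id of every record, in record order.
#' @return list of `list(train, test)` integer index pairs, one per fold;
#'   records of blind proteins appear in no fold.
#' @export
cv_folds <- function(plan, protein_ids) {
  lapply(seq_len(plan$k), function(f) {
    fold_assign <- plan$fold_of[protein_ids]
    list(train = which(!is.na(fold_assign) & fold_assign != f),
         test = which(!is.na(fold_assign) & fold_assign == f))
  })
}
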