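#' Train the two-layer stability cascade
#'
#' Layer 1 is a random forest separating stability-decreasing variants
#' from the rest, trained on a balanced set in which the "no decrease"
#' class combines equal halves of increase and no-effect cases; layer 2
#' separates increase from no-effect on a balanced subset of those two
#' classes. Each layer uses its own selected feature list. Missing
#' feature values (e.g. absent external descriptors) are imputed with
#' training-set medians, which are stored in the model manifest.
#'
#' @param x feature matrix (rows = records, named columns).
#' @param labels three-class labels aligned with the rows of `x`.
#' @param features1,features2 feature-name vectors for layers 1 and 2.
#' @param ntree trees per forest.
#' @param seed RNG seed (balancing and forest growth).
#' @return object of class `two_layer_model`.
#' @export
train_two_layer <- function(x, labels, features1, features2, ntree = 300,
                            seed = 1) {
  stopifnot(length(features1) >= 1, length(features2) >= 1)
  labels <- factor(as.character(labels), levels = STABILITY_CLASSES)
  if (any(is.na(labels))) stop("labels outside the three classes",
                               call. = FALSE)
  if (nlevels(droplevels(labels)) < 3) {
    stop("all three classes must be present for training", call. = FALSE)
  }
  missing1 <- setdiff(features1, colnames(x))
  missing2 <- setdiff(features2, colnames(x))
  if (length(missing1) || length(missing2)) {
    stop("feature(s) absent from the table: ",
         paste(c(missing1, missing2), collapse = ", "), call. = FALSE)
  }
  used <- union(features1, features2)
  medians <- apply(x[, used, drop = FALSE], 2, median, na.rm = TRUE)
  impute <- function(m) {
    for (j in colnames(m)) {
      miss <- is.na(m[, j])
      if (any(miss)) m[miss, j] <- medians[[j]]
    }
    m
  }

  b1 <- balance_binary(labels, "layer1", seed)
  x1 <- impute(x[b1$idx, features1, drop = FALSE])
  set.seed(seed)
  layer1 <- randomForest::randomForest(x = as.data.frame(x1), y = b1$y,
                                       ntree = ntree)

  sub <- labels %in% c("increase", "no_effect")
  b2 <- balance_binary(labels, "layer2", seed)
  x2 <- impute(x[b2$idx, features2, drop = FALSE])
  set.seed(seed + 1)
  layer2 <- randomForest::randomForest(x = as.data.frame(x2), y = b2$y,
                                       ntree = ntree)

  structure(list(
    layer1 = layer1, layer2 = layer2,
    features1 = features1, features2 = features2,
    medians = medians,
    manifest = list(ntree = ntree, seed = seed,
                    balancing = list(layer1 = "decrease vs equal halves of increase+no_effect",
                                     layer2 = "undersampled increase vs no_effect",
                                     layer1_resampled = b1$resampled),
                    n_train = nrow(x),
                    registry_hash = registry_hash(colnames(x)))),
    class = "two_layer_model")
}

registry_hash <- function(names) {
  # order-sensitive checksum so feature-order drift is detected at load
  sum(vapply(seq_along(names), function(i)
    i * sum(utf8ToInt(names[i])), numeric(1))) %% 2^31
}

impute_newdata <- function(model, newdata, features) {
  absent <- setdiff(features, colnames(newdata))
  if (length(absent)) {
    stop("missing non-imputable feature(s): ",
         paste(absent, collapse = ", "), call. = FALSE)
  }
  m <- newdata[, features, drop = FALSE]
  for (j in features) {
    miss <- is.na(m[, j])
    if (any(miss)) m[miss, j] <- model$medians[[j]]
  }
  m
}

#' Predict stability classes with the cascade
#'
#' Layer 1 votes first: a decrease vote fraction of at least 0.5 is
#' terminal. Otherwise layer 2 decides between increase and no-effect,
#' again at the 0.5 vote threshold. Per-layer vote fractions are
#' returned alongside the labels.
#'
#' @param object a `two_layer_model`.
#' @param newdata feature matrix with named columns covering both feature
#'   lists (missing values imputed with stored training medians).
#' @param ... unused.
#' @return data.frame with `label` (factor over the three classes),
#'   `score_decrease` (layer-1 decrease vote fraction) and
#'   `score_increase` (layer-2 increase vote fraction), one row per input
#'   row, order preserved.
#' @export
predict.two_layer_model <- function(object, newdata, ...) {
  if (is.null(dim(newdata))) newdata <- t(as.matrix(newdata))
  n <- nrow(newdata)
  if (n == 0) {
    return(data.frame(label = factor(character(),
                                     levels = STABILITY_CLASSES),
                      score_decrease = numeric(),
                      score_increase = numeric()))
  }
  x1 <- impute_newdata(object, newdata, object$features1)
  v1 <- predict(object$layer1, as.data.frame(x1), type = "vote")
  score_dec <- v1[, "decrease"]
  x2 <- impute_newdata(object, newdata, object$features2)
  v2 <- predict(object$layer2, as.data.frame(x2), type = "vote")
  score_inc <- v2[, "increase"]
  label <- ifelse(score_dec >= 0.5, "decrease",
                  ifelse(score_inc >= 0.5, "increase", "no_effect"))
  data.frame(label = factor(label, levels = STABILITY_CLASSES),
             score_decrease = as.numeric(score_dec),
             score_increase = as.numeric(score_inc),
             row.names = rownames(newdata))
}

#' Row-wise batch prediction
#'
#' Equivalent to [predict.two_layer_model()] on the whole table; kept as
#' an explicit verb for pipeline scripts.
#'
#' @param model a `two_layer_model`.
#' @param table feature matrix.
#' @return as [predict.two_layer_model()].
#' @export
predict_batch <- function(model, table) {
  predict(model, table)
}
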