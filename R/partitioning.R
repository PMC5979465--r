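#' Percent sequence identity from a global alignment
#'
#' Needleman-Wunsch global alignment (BLOSUM62, gap opening 10, gap
#' extension 0.5, via Biostrings) with identity defined conservatively as
#' the number of identical aligned positions over the full alignment
#' length including gaps. Symmetric in its arguments.
#'
#' @param seq_a,seq_b protein sequences.
#' @return identity in percent (0--100).
#' @export
pairwise_identity <- function(seq_a, seq_b) {
  stopifnot(nzchar(seq_a), nzchar(seq_b))
  aln <- Biostrings::pairwiseAlignment(seq_a, seq_b, type = "global",
                                       substitutionMatrix = "BLOSUM62",
                                       gapOpening = 10, gapExtension = 0.5)
  Biostrings::pid(aln, type = "PID1")
}

#' Cluster proteins by sequence identity
#'
#' Single-linkage components of the graph whose edges join protein pairs
#' above the identity threshold. Single linkage is the safest closure for
#' keeping all related proteins in one cross-validation partition: any
#' chain of pairwise-similar proteins ends up in the same cluster.
#'
#' @param sequences named character vector of protein sequences.
#' @param threshold identity threshold in percent (edges where identity
#'   exceeds it).
#' @return object of class `homology_clusters`: list with `clusters`
#'   (list of protein-id character vectors, deterministic order) and
#'   `threshold`.
#' @export
cluster_proteins <- function(sequences, threshold = 30) {
  ids <- names(sequences)
  stopifnot(length(ids) >= 1, !is.null(ids))
  n <- length(ids)
  adj <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  if (n > 1) {
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):n) {
        adj[i, j] <- adj[j, i] <-
          pairwise_identity(sequences[[i]], sequences[[j]]) > threshold
      }
    }
  }
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                           diag = FALSE)
  comp <- igraph::components(g)
  clusters <- split(ids, comp$membership)
  clusters <- lapply(clusters, sort)
  clusters <- clusters[order(vapply(clusters, `[`, "", 1))]
  names(clusters) <- NULL
  structure(list(clusters = clusters, threshold = threshold),
            class = "homology_clusters")
}

#' Homology-aware cross-validation plan
#'
#' Builds a blind test set and a k-fold assignment at the protein level
#' such that no homology cluster is split: the blind set is drawn only
#' from singleton clusters (proteins with no close homolog anywhere, so
#' the test is maximally stringent), and the remaining clusters are
#' assigned greedily, largest first, to the currently smallest fold by
#' variant count.
#'
#' @param clusters a `homology_clusters`.
#' @param variant_counts named integer vector: variants per protein_id.
#' @param k number of folds.
#' @param blind_fraction target fraction of variants in the blind set.
#' @param seed RNG seed for the blind-set draw.
#' @return object of class `cv_plan`: list with `fold_of` (named integer
#'   vector over training proteins), `blind` (character vector of blind
#'   protein ids), `k`, `seed`.
#' @export
make_cv_plan <- function(clusters, variant_counts, k = 5,
                         blind_fraction = 0.1, seed = 1) {
  cl <- clusters$clusters
  if (length(cl) < k) {
    stop("fewer clusters (", length(cl), ") than folds (", k, ")",
         call. = FALSE)
  }
  count_of <- function(ids) sum(variant_counts[ids])
  singletons <- which(vapply(cl, length, integer(1)) == 1)
  total <- sum(variant_counts)
  target <- blind_fraction * total
  blind <- character(0)
  if (target > 0 && length(singletons) > 0) {
    set.seed(seed)
    pool <- sample(singletons)
    take <- 0
    for (s in pool) {
      if (length(cl) - length(blind) - 1 < k) break
      if (take >= target) break
      blind <- c(blind, cl[[s]])
      take <- take + count_of(cl[[s]])
    }
  }
  rest <- cl[!vapply(cl, function(x) all(x %in% blind), logical(1))]
  sizes <- vapply(rest, count_of, numeric(1))
  ord <- order(-sizes, vapply(rest, `[`, "", 1))
  fold_load <- numeric(k)
  fold_of <- integer(0)
  for (i in ord) {
    f <- which.min(fold_load)
    fold_load[f] <- fold_load[f] + sizes[i]
    fold_of <- c(fold_of, setNames(rep(f, length(rest[[i]])), rest[[i]]))
  }
  structure(list(fold_of = fold_of, blind = sort(blind), k = k,
                 seed = seed), class = "cv_plan")
}

#' Balanced training sets for the two cascade layers
#'
#' Layer 1 (decrease vs no-decrease) keeps every decrease case as the
#' positive class and assembles the negative "no decrease" class from
#' equal halves of increase and no-effect cases so the two classes have
#' the same total; the larger side of each half is undersampled, and a
#' half is resampled with replacement only when it cannot otherwise fill
#' its share (flagged). Layer 2 (increase vs no-effect) undersamples the
#' larger class to the size of the smaller. Seeded and reproducible.
#'
#' @param labels factor/character vector of the three-class labels.
#' @param task `"layer1"` or `"layer2"`.
#' @param seed RNG seed.
#' @return list with `idx` (integer indices into `labels`), `y` (the
#'   binary factor aligned with `idx`), and `resampled` (logical flag).
#' @export
balance_binary <- function(labels, task = c("layer1", "layer2"), seed = 1) {
  task <- match.arg(task)
  labels <- as.character(labels)
  idx_inc <- which(labels == "increase")
  idx_no <- which(labels == "no_effect")
  idx_dec <- which(labels == "decrease")
  if (!length(idx_inc) || !length(idx_no) || !length(idx_dec)) {
    stop("all three classes must be present for balancing", call. = FALSE)
  }
  set.seed(seed)
  draw <- function(pool, m) {
    if (length(pool) >= m) sample(pool, m)
    else c(pool, sample(pool, m - length(pool), replace = TRUE))
  }
  resampled <- FALSE
  if (task == "layer1") {
    n_pos <- length(idx_dec)
    m_inc <- n_pos %/% 2
    m_no <- n_pos - m_inc
    if (length(idx_inc) < m_inc || length(idx_no) < m_no) resampled <- TRUE
    neg <- c(draw(idx_inc, m_inc), draw(idx_no, m_no))
    idx <- c(idx_dec, neg)
    y <- factor(c(rep("decrease", n_pos), rep("no_decrease", length(neg))),
                levels = c("no_decrease", "decrease"))
  } else {
    m <- min(length(idx_inc), length(idx_no))
    idx <- c(draw(idx_inc, m), draw(idx_no, m))
    y <- factor(c(rep("increase", m), rep("no_effect", m)),
                levels = c("no_effect", "increase"))
  }
  list(idx = idx, y = y, resampled = resampled)
}

#' Serialize a CV plan as TSV
#'
#' @param plan a `cv_plan`.
#' @param path output path; a sibling `<path>.manifest.json` records the
#'   seed and fold count.
#' @export
write_cv_plan <- function(plan, path) {
  df <- rbind(data.frame(protein_id = names(plan$fold_of),
                         assignment = paste0("fold", plan$fold_of),
                         stringsAsFactors = FALSE),
              data.frame(protein_id = plan$blind, assignment = "blind",
                         stringsAsFactors = FALSE))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(list(k = plan$k, seed = plan$seed),
                       paste0(path, ".manifest.json"), auto_unbox = TRUE)
  invisible(path)
}
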