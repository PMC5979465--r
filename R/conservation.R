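#' Construct a multiple sequence alignment object
#'
#' @param sequences character vector of aligned sequences (gap `-`), all
#'   the same length; the first (or `ref_index`-th) row is the query.
#' @param ref_index which row is the reference protein.
#' @return an object of class `msa`.
#' @export
new_msa <- function(sequences, ref_index = 1L) {
  sequences <- toupper(as.character(sequences))
  if (length(unique(nchar(sequences))) != 1) {
    stop("all MSA rows must have equal length", call. = FALSE)
  }
  stopifnot(ref_index >= 1, ref_index <= length(sequences))
  structure(list(sequences = sequences, ref_index = as.integer(ref_index),
                 length = nchar(sequences[1])),
            class = "msa")
}

#' Read an MSA from aligned FASTA or Clustal format
#'
#' The dialect is auto-detected from the file content: a leading
#' `CLUSTAL` line selects the Clustal reader, otherwise aligned FASTA is
#' assumed. Reading is delegated to [Biostrings::readAAMultipleAlignment].
#'
#' @param path alignment file.
#' @param ref_index row index of the reference protein (default first).
#' @return an `msa` object.
#' @export
read_msa <- function(path, ref_index = 1L) {
  first <- readLines(path, n = 1)
  fmt <- if (grepl("^CLUSTAL", first, ignore.case = TRUE)) "clustal"
         else "fasta"
  aln <- Biostrings::readAAMultipleAlignment(path, format = fmt)
  new_msa(as.character(Biostrings::unmasked(aln)), ref_index)
}

msa_matrix <- function(msa) {
  do.call(rbind, strsplit(msa$sequences, ""))
}

#' Map reference positions to alignment columns
#'
#' Columns where the reference row carries a gap are never assigned to a
#' reference position; every non-gap reference residue maps to exactly one
#' column.
#'
#' @param msa an `msa`.
#' @return integer vector: element i is the alignment column of reference
#'   position i.
#' @export
msa_ref_map <- function(msa) {
  ref <- strsplit(msa$sequences[msa$ref_index], "")[[1]]
  which(ref != "-")
}

column_counts <- function(mat, column) {
  col <- mat[, column]
  col <- col[col %in% AA20]
  tab <- table(factor(col, levels = AA20))
  as.numeric(tab)
}

#' Per-column information content
#'
#' Conservation in bits: `log2(20) + sum(p * log2 p)` over the 20 amino
#' acids, with gaps excluded from the counts. A fully conserved column
#' scores `log2(20) ~ 4.322` bits; a column uniform over all residues
#' scores 0. With a positive pseudocount the observed counts are smoothed
#' towards the background before computing the entropy.
#'
#' @param msa an `msa`.
#' @param column alignment column index.
#' @param pseudocount total pseudocount mass distributed by `background`.
#' @param background 20 background frequencies in `AA20` order.
#' @return bits, with attribute `degenerate = TRUE` when only the
#'   reference row contributes a residue.
#' @export
column_information_content <- function(msa, column, pseudocount = 0,
                                       background = rep(1 / 20, 20)) {
  mat <- msa_matrix(msa)
  counts <- column_counts(mat, column)
  non_ref <- mat[-msa$ref_index, column, drop = TRUE]
  degenerate <- length(non_ref) > 0 && !any(non_ref %in% AA20)
  n <- sum(counts)
  if (n == 0) stop("column ", column, " contains no residues", call. = FALSE)
  p <- (counts + pseudocount * background) / (n + pseudocount)
  terms <- ifelse(p > 0, p * log2(p), 0)
  ic <- log2(20) + sum(terms)
  attr(ic, "degenerate") <- degenerate
  ic
}

#' Position-specific scoring matrix from an MSA
#'
#' Log-odds of the smoothed column frequency against the background:
#' `score(pos, a) = log2(((n_a + pc * bg_a) / (N + pc)) / bg_a)`, computed
#' for every reference position (columns where the reference is gapped are
#' skipped). A positive pseudocount is required so every score is finite.
#'
#' @param msa an `msa`.
#' @param pseudocount total pseudocount mass (> 0), distributed by
#'   `background`.
#' @param background 20 background frequencies in `AA20` order.
#' @return numeric matrix, rows = reference positions, columns = `AA20`.
#' @export
build_pssm <- function(msa, pseudocount = 1, background = rep(1 / 20, 20)) {
  if (pseudocount <= 0) {
    stop("pseudocount must be > 0 to keep log-odds finite", call. = FALSE)
  }
  stopifnot(length(background) == 20, all(background > 0))
  mat <- msa_matrix(msa)
  cols <- msa_ref_map(msa)
  scores <- matrix(NA_real_, nrow = length(cols), ncol = 20,
                   dimnames = list(NULL, AA20))
  for (i in seq_along(cols)) {
    counts <- column_counts(mat, cols[i])
    n <- sum(counts)
    p <- (counts + pseudocount * background) / (n + pseudocount)
    scores[i, ] <- log2(p / background)
  }
  scores
}

cramers_v <- function(a, b) {
  keep <- a %in% AA20 & b %in% AA20
  a <- a[keep]; b <- b[keep]
  if (length(a) < 2) return(0)
  fa <- factor(a); fb <- factor(b)
  if (nlevels(fa) < 2 || nlevels(fb) < 2) return(0)
  tab <- table(fa, fb)
  n <- sum(tab)
  e <- outer(rowSums(tab), colSums(tab)) / n
  chi2 <- sum((tab - e)^2 / e)
  k <- min(nrow(tab), ncol(tab))
  sqrt(chi2 / (n * (k - 1)))
}

#' Co-evolution proxy scores per reference position
#'
#' Pairwise column association is measured by Cramer's V on the residue
#' identities (gaps excluded pairwise). For each reference position the
#' maximum association with any other mapped column is reported, together
#' with a binary co-evolution call at the threshold, membership in a
#' co-evolving group (a connected component of the thresholded association
#' graph with at least two members), and the number of such groups the
#' position belongs to. Alignments with fewer than `min_depth` non-
#' reference rows are considered too shallow and return all-zero tuples
#' flagged `low_depth`.
#'
#' @param msa an `msa`.
#' @param correlation_threshold association threshold for a co-evolution
#'   call.
#' @param min_depth minimum number of non-reference rows.
#' @return data.frame (one row per reference position): `position`,
#'   `is_coevolving`, `max_cor`, `is_coevolving_grp`, `grp_count`; with
#'   attribute `low_depth`.
#' @export
coevolution_proxy <- function(msa, correlation_threshold = 0.8,
                              min_depth = 10) {
  cols <- msa_ref_map(msa)
  npos <- length(cols)
  out <- data.frame(position = seq_len(npos), is_coevolving = 0L,
                    max_cor = 0, is_coevolving_grp = 0L, grp_count = 0L)
  depth <- length(msa$sequences) - 1L
  if (depth < min_depth) {
    attr(out, "low_depth") <- TRUE
    return(out)
  }
  attr(out, "low_depth") <- FALSE
  mat <- msa_matrix(msa)
  assoc <- matrix(0, npos, npos)
  for (i in seq_len(npos - 1)) {
    for (j in (i + 1):npos) {
      v <- cramers_v(mat[, cols[i]], mat[, cols[j]])
      assoc[i, j] <- v
      assoc[j, i] <- v
    }
  }
  if (npos > 1) {
    out$max_cor <- apply(assoc, 1, max)
    out$is_coevolving <- as.integer(out$max_cor >= correlation_threshold)
    adj <- assoc >= correlation_threshold
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected",
                                             diag = FALSE)
    comp <- igraph::components(g)
    in_group <- comp$csize[comp$membership] >= 2
    out$is_coevolving_grp <- as.integer(in_group)
    out$grp_count <- as.integer(in_group)
  }
  out
}

#' Full conservation profile of the reference protein
#'
#' Combines information content, PSSM scores and the co-evolution proxy
#' into one table indexed by reference position.
#'
#' @param msa an `msa`.
#' @param pseudocount,background passed to [build_pssm()]; the information
#'   content uses the raw (pseudocount-free) column frequencies.
#' @param correlation_threshold passed to [coevolution_proxy()].
#' @return data.frame of class `conservation_profile`: `position`, `wt`,
#'   `ic`, `pssm_A` ... `pssm_V`, and the four co-evolution columns.
#' @export
conservation_profile <- function(msa, pseudocount = 1,
                                 background = rep(1 / 20, 20),
                                 correlation_threshold = 0.8) {
  cols <- msa_ref_map(msa)
  ref <- strsplit(msa$sequences[msa$ref_index], "")[[1]]
  ic <- vapply(cols, function(cl)
    as.numeric(column_information_content(msa, cl)), numeric(1))
  pssm <- build_pssm(msa, pseudocount, background)
  colnames(pssm) <- paste0("pssm_", AA20)
  coev <- coevolution_proxy(msa, correlation_threshold)
  out <- data.frame(position = seq_along(cols), wt = ref[cols], ic = ic,
                    pssm, coev[, c("is_coevolving", "max_cor",
                                   "is_coevolving_grp", "grp_count")],
                    stringsAsFactors = FALSE)
  class(out) <- c("conservation_profile", "data.frame")
  out
}

#' Write a conservation profile as TSV
#'
#' @param profile a `conservation_profile`.
#' @param path output path.
#' @export
write_profile <- function(profile, path) {
  write.table(profile, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
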