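#' Fixture specification for synthetic variant corpora
#'
#' The generator defaults emulate the curated benchmark's study
#' conditions: class proportions of about 1:2:4 for increase : no effect
#' : decrease, ddG limited to [-17.4, 23.0] kcal/mol, measurement pH in
#' [2.7, 9.6] and temperatures in [0, 89] degrees C. Class-conditional
#' ddG values are truncated normals (decrease mean -2, increase mean
#' +1.5, sd 1) and no-effect values are uniform on the neutral band.
#'
#' @param n_proteins,variants_per_protein corpus dimensions.
#' @param class_proportions unnormalized sampling weights for increase,
#'   no_effect, decrease.
#' @param ddg_range,ph_range,temperature_range closed ranges.
#' @param protein_length length of the generated reference proteins.
#' @param n_homolog_pairs number of planted homolog pairs (~90%
#'   identity) among the proteins.
#' @param seed RNG seed (mandatory).
#' @return list of class `fixture_spec`.
#' @export
fixture_spec <- function(n_proteins = 12, variants_per_protein = 10,
                         class_proportions = c(increase = 1, no_effect = 2,
                                               decrease = 4),
                         ddg_range = c(-17.4, 23.0),
                         ph_range = c(2.7, 9.6),
                         temperature_range = c(0, 89),
                         protein_length = 80,
                         n_homolog_pairs = 0,
                         seed) {
  if (missing(seed)) stop("seed is mandatory for fixtures", call. = FALSE)
  stopifnot(all(class_proportions > 0), n_proteins >= 1,
            2 * n_homolog_pairs <= n_proteins)
  structure(as.list(environment()), class = "fixture_spec")
}

random_protein <- function(length) {
  paste(sample(AA20, length, replace = TRUE), collapse = "")
}

mutate_fraction <- function(sequence, fraction) {
  chars <- strsplit(sequence, "")[[1]]
  n_mut <- max(1, round(fraction * length(chars)))
  pos <- sample(seq_along(chars), n_mut)
  for (p in pos) chars[p] <- sample(setdiff(AA20, chars[p]), 1)
  paste(chars, collapse = "")
}

rtruncnorm1 <- function(mean, sd, lower, upper) {
  repeat {
    x <- stats::rnorm(1, mean, sd)
    if (x >= lower && x <= upper) return(x)
  }
}

sample_ddg <- function(class, range) {
  switch(class,
         increase = rtruncnorm1(1.5, 1, 0.5 + 1e-6, range[2]),
         decrease = rtruncnorm1(-2, 1, range[1], -0.5 - 1e-6),
         no_effect = stats::runif(1, -0.5, 0.5))
}

#' Generate a synthetic variant corpus
#'
#' Random unrelated protein sequences (optionally with planted homolog
#' pairs at ~90% identity), variant records whose ddG values are drawn
#' from class-conditional distributions, and a ground-truth table of the
#' intended labels.
#'
#' @param spec a [fixture_spec()].
#' @return list with `records` (a harmonized `variant_table`),
#'   `sequences` (named character vector) and `truth` (data.frame
#'   `record_id`, `label`).
#' @export
generate_variant_corpus <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  set.seed(spec$seed)
  n_prot <- spec$n_proteins
  ids <- sprintf("P%03d", seq_len(n_prot))
  sequences <- character(n_prot)
  i <- 1
  pair <- 0
  while (i <= n_prot) {
    sequences[i] <- random_protein(spec$protein_length)
    if (pair < spec$n_homolog_pairs && i + 1 <= n_prot) {
      sequences[i + 1] <- mutate_fraction(sequences[i], 0.1)
      pair <- pair + 1
      i <- i + 2
    } else {
      i <- i + 1
    }
  }
  names(sequences) <- ids

  p <- spec$class_proportions / sum(spec$class_proportions)
  classes <- c("increase", "no_effect", "decrease")
  rows <- list()
  rid <- 0
  for (prot in ids) {
    chars <- strsplit(sequences[[prot]], "")[[1]]
    for (v in seq_len(spec$variants_per_protein)) {
      rid <- rid + 1
      pos <- sample(seq_along(chars), 1)
      wt <- chars[pos]
      mut <- sample(setdiff(AA20, wt), 1)
      cls <- sample(classes, 1, prob = p)
      rows[[rid]] <- data.frame(
        record_id = sprintf("R%05d", rid), protein_id = prot,
        sequence_ref = prot, wt_aa = wt, position = pos, mut_aa = mut,
        ddg = sample_ddg(cls, spec$ddg_range), ddg_unit = "kcal/mol",
        temperature = stats::runif(1, spec$temperature_range[1],
                                   spec$temperature_range[2]),
        ph = stats::runif(1, spec$ph_range[1], spec$ph_range[2]),
        salt_molar = stats::runif(1, 0, 0.15), method = "DSC",
        pdb_ref = NA, background_variants = NA, state_flag = "folded",
        truth_label = cls, stringsAsFactors = FALSE)
    }
  }
  records <- do.call(rbind, rows)
  truth <- data.frame(record_id = records$record_id,
                      label = records$truth_label,
                      stringsAsFactors = FALSE)
  records$truth_label <- NULL
  class(records) <- c("variant_table", "data.frame")
  list(records = records, sequences = sequences, truth = truth)
}

#' Generate a feature table with planted signal
#'
#' Noise columns are standard normal; informative columns are mean-
#' shifted per class by the effect size (class k at `(k - 2) *
#' effect_size` for the three classes in `STABILITY_CLASSES` order, or
#' `+- effect_size / 2` for two classes).
#'
#' @param n_rows rows per class (balanced).
#' @param n_features total number of columns.
#' @param n_informative number of mean-shifted columns.
#' @param effect_size shift magnitude, in standard deviations.
#' @param seed RNG seed.
#' @param n_classes 2 or 3.
#' @return list with `x` (matrix, columns `f001`...), `y` (factor) and
#'   `informative` (column names carrying signal).
#' @export
generate_feature_table <- function(n_rows, n_features, n_informative,
                                   effect_size, seed, n_classes = 3) {
  stopifnot(n_informative <= n_features, n_classes %in% c(2, 3))
  set.seed(seed)
  classes <- if (n_classes == 3) STABILITY_CLASSES
             else c("no_effect", "decrease")
  per <- ceiling(n_rows / length(classes))
  y <- factor(rep(classes, each = per)[seq_len(n_rows)], levels = classes)
  x <- matrix(stats::rnorm(n_rows * n_features), n_rows, n_features,
              dimnames = list(NULL, sprintf("f%03d", seq_len(n_features))))
  shifts <- if (n_classes == 3) (seq_len(3) - 2) * effect_size
            else c(-0.5, 0.5) * effect_size
  informative <- colnames(x)[seq_len(n_informative)]
  for (j in informative) {
    x[, j] <- x[, j] + shifts[as.integer(y)]
  }
  # shuffle rows so class blocks are not contiguous
  ord <- sample(n_rows)
  list(x = x[ord, , drop = FALSE], y = y[ord], informative = informative)
}

#' Write a corrupted variant file with known ground truth
#'
#' Starts from a clean corpus and plants the classic curation issues:
#' kJ/mol units, Kelvin temperatures, flipped sign conventions,
#' duplicates, short peptides, unfolded-protein and partial-stage
#' records, and out-of-window pH measurements shadowed by an in-window
#' one. The returned ground truth states, per record, whether curation
#' should keep, correct or reject it and with which reason code.
#'
#' @param path output TSV path.
#' @param n_clean number of clean records to start from.
#' @param plan named integer vector over the corruption types `kj`,
#'   `kelvin`, `sign`, `dup`, `short`, `unfolded`, `stage`, `ph`.
#' @param seed RNG seed.
#' @return data.frame ground truth: `record_id`, `expect`
#'   (`kept`/`corrected`/`rejected`), `reason`.
#' @export
generate_corrupted_variant_file <- function(path, n_clean = 10,
                                            plan = c(kj = 2, kelvin = 1,
                                                     dup = 2),
                                            seed = 1) {
  supported <- c("kj", "kelvin", "sign", "dup", "short", "unfolded",
                 "stage", "ph")
  if (length(plan) && !all(names(plan) %in% supported)) {
    stop("unsupported corruption type(s): ",
         paste(setdiff(names(plan), supported), collapse = ", "),
         call. = FALSE)
  }
  spec <- fixture_spec(n_proteins = max(2, ceiling(n_clean / 5)),
                       variants_per_protein = 5, seed = seed)
  corpus <- generate_variant_corpus(spec)
  rec <- corpus$records[seq_len(n_clean), , drop = FALSE]
  rec$ddg_sign <- "stabilizing_positive"
  # keep conditions inside the curation window so clean rows survive
  rec$ph <- round(stats::runif(n_clean, 5.2, 8.8), 2)
  truth <- data.frame(record_id = rec$record_id, expect = "kept",
                      reason = "", stringsAsFactors = FALSE)
  get_n <- function(type) if (type %in% names(plan)) plan[[type]] else 0L
  pool <- seq_len(n_clean)
  take <- function(n) {
    stopifnot(length(pool) >= n)
    out <- pool[seq_len(n)]
    pool <<- pool[-seq_len(n)]
    out
  }
  mark <- function(i, expect, reason = "") {
    truth$expect[i] <<- expect
    truth$reason[i] <<- reason
  }
  extra <- list()

  for (i in take(get_n("kj"))) {
    rec$ddg[i] <- rec$ddg[i] * KJ_PER_KCAL
    rec$ddg_unit[i] <- "kJ/mol"
    mark(i, "corrected", "unit_conversion")
  }
  for (i in take(get_n("kelvin"))) {
    rec$temperature[i] <- rec$temperature[i] + KELVIN_OFFSET
    mark(i, "corrected", "kelvin_temperature")
  }
  for (i in take(get_n("sign"))) {
    rec$ddg[i] <- -rec$ddg[i]
    rec$ddg_sign[i] <- "destabilizing_positive"
    mark(i, "corrected", "sign_flip")
  }
  for (i in take(get_n("unfolded"))) {
    rec$state_flag[i] <- "unfolded"
    mark(i, "rejected", "unfolded_protein")
  }
  for (i in take(get_n("stage"))) {
    rec$state_flag[i] <- "stage_partial"
    mark(i, "rejected", "stage_value")
  }
  for (i in take(get_n("ph"))) {
    # plant an out-of-window duplicate measurement of the same variant
    bad <- rec[i, , drop = FALSE]
    bad$record_id <- paste0(bad$record_id, "_lowph")
    bad$ph <- 3.0
    bad$ddg <- bad$ddg + 0.05
    extra[[length(extra) + 1]] <- bad
    truth <- rbind(truth, data.frame(record_id = bad$record_id,
                                     expect = "rejected",
                                     reason = "out_of_range_ph_superseded",
                                     stringsAsFactors = FALSE))
  }
  for (i in seq_len(get_n("dup"))) {
    src <- rec[((i - 1) %% n_clean) + 1, , drop = FALSE]
    dup <- src
    dup$record_id <- paste0(src$record_id, "_dup")
    extra[[length(extra) + 1]] <- dup
    truth <- rbind(truth, data.frame(record_id = dup$record_id,
                                     expect = "rejected",
                                     reason = "duplicate",
                                     stringsAsFactors = FALSE))
  }
  out <- rbind(rec, do.call(rbind, extra))
  if (get_n("short") > 0) {
    short_seq <- random_protein(12)
    for (i in seq_len(get_n("short"))) {
      row <- rec[1, , drop = FALSE]
      row$record_id <- sprintf("RSHORT%02d", i)
      row$protein_id <- row$sequence_ref <- "PSHORT"
      row$position <- i
      row$wt_aa <- substr(short_seq, i, i)
      row$mut_aa <- sample(setdiff(AA20, row$wt_aa), 1)
      out <- rbind(out, row)
      truth <- rbind(truth, data.frame(record_id = row$record_id,
                                       expect = "rejected",
                                       reason = "short_peptide",
                                       stringsAsFactors = FALSE))
    }
    corpus$sequences <- c(corpus$sequences, PSHORT = short_seq)
  }
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  attr(truth, "sequences") <- corpus$sequences
  truth
}

#' Generate a toy MSA with planted structure
#'
#' The reference row plus `depth` homolog rows. Conserved positions carry
#' the reference residue in every row; co-evolving column pairs share a
#' per-row hidden state mapped to residues (perfect association); all
#' other columns are i.i.d. uniform over the alphabet.
#'
#' @param depth number of non-reference rows.
#' @param length alignment length (no gaps are planted).
#' @param conserved_positions positions held invariant.
#' @param coevolving_pairs list of 2-element position vectors.
#' @param seed RNG seed.
#' @return an `msa` (reference row first).
#' @export
generate_toy_msa <- function(depth, length, conserved_positions = integer(),
                             coevolving_pairs = list(), seed = 1) {
  stopifnot(all(unlist(c(conserved_positions, coevolving_pairs)) <= length))
  set.seed(seed)
  ref <- sample(AA20, length, replace = TRUE)
  mat <- matrix(sample(AA20, (depth + 1) * length, replace = TRUE),
                nrow = depth + 1)
  mat[1, ] <- ref
  for (p in conserved_positions) mat[, p] <- ref[p]
  state_codes <- c("A", "C", "D", "E")
  partner_codes <- c("F", "G", "H", "I")
  for (pair in coevolving_pairs) {
    states <- sample(1:4, depth + 1, replace = TRUE)
    mat[, pair[1]] <- state_codes[states]
    mat[, pair[2]] <- partner_codes[states]
  }
  new_msa(apply(mat, 1, paste, collapse = ""), ref_index = 1L)
}

#' Write an MSA as aligned FASTA
#'
#' @param msa an `msa`.
#' @param path output path.
#' @param names row names (default `ref`, `hom1`, ...).
#' @export
write_msa <- function(msa, path, names = NULL) {
  if (is.null(names)) {
    names <- c("ref", paste0("hom", seq_len(length(msa$sequences) - 1)))
    names <- append(names[-1], "ref", after = msa$ref_index - 1)
  }
  writeLines(paste0(">", names, "\n", msa$sequences), path)
  invisible(path)
}

#' Write sequences as FASTA
#'
#' @param sequences named character vector.
#' @param path output path.
#' @export
write_fasta <- function(sequences, path) {
  writeLines(paste0(">", names(sequences), "\n", sequences), path)
  invisible(path)
}

#' Read sequences from FASTA
#'
#' @param path FASTA file.
#' @return named character vector.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readAAStringSet(path)
  setNames(as.character(x), names(x))
}
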