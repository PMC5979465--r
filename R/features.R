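#' The named feature registry
#'
#' The variant descriptor has 1106 slots drawn from nine families:
#' experimental conditions (2), alignment conservation (3), co-evolution
#' (4), AAindex physicochemical encodings (617), substitution one-hots
#' over the 20x20 residue pairs (400) and over 6x6 physicochemical groups
#' (36), neighbourhood residue counts (20) and class counts (5), and
#' external per-protein descriptors (19) accepted as a precomputed
#' sidecar. Order is stable across runs; models address features by name.
#'
#' @param table an `aaindex_table` (defaults to the packaged one), whose
#'   accession order fixes the 617 AAindex slot names.
#' @return data.frame of class `feature_registry` with columns `name`,
#'   `family`.
#' @export
feature_registry <- function(table = default_aaindex_table()) {
  stopifnot(inherits(table, "aaindex_table"), table$n_features == 617L)
  fam <- function(names, family) data.frame(name = names, family = family,
                                            stringsAsFactors = FALSE)
  grid20 <- expand.grid(mut = AA20, wt = AA20, stringsAsFactors = FALSE)
  g6 <- names(AA_GROUPS6)
  grid6 <- expand.grid(mut = g6, wt = g6, stringsAsFactors = FALSE)
  reg <- rbind(
    fam(c("temperature_c", "ph"), "condition"),
    fam(c("ic", "pssm_wt", "pssm_mut"), "conservation"),
    fam(c("is_coevolving", "max_cor", "is_coevolving_grp", "grp_count"),
        "coevolution"),
    fam(paste0("aaindex_", c(names(table$indices), names(table$matrices))),
        "aaindex"),
    fam(paste0("vt_", grid20$wt, grid20$mut), "vartype20x20"),
    fam(paste0("vg_", grid6$wt, "_", grid6$mut), "vartype6x6"),
    fam(paste0("nb_", AA20), "neighborhood_counts"),
    fam(paste0("nbc_", names(AA_CLASSES5)), "neighborhood_classes"),
    fam(sprintf("external_%02d", 1:19), "external_protein"))
  stopifnot(nrow(reg) == 1106L, !anyDuplicated(reg$name))
  class(reg) <- c("feature_registry", "data.frame")
  reg
}

#' Experimental-condition features
#'
#' @param record one row of a harmonized `variant_table`.
#' @return named vector `(temperature_c, ph)`.
#' @export
condition_features <- function(record) {
  if (is.na(record$ph)) stop("pH is mandatory for prediction", call. = FALSE)
  if (is.na(record$temperature)) {
    stop("temperature is mandatory for prediction", call. = FALSE)
  }
  c(temperature_c = as.numeric(record$temperature), ph = as.numeric(record$ph))
}

#' Conservation features at the variant site
#'
#' Information content of the site plus the PSSM log-odds of the
#' wild-type and substituting residues.
#'
#' @param profile a `conservation_profile`.
#' @param position 1-based reference position.
#' @param wt_aa,mut_aa residues.
#' @return named vector `(ic, pssm_wt, pssm_mut)`.
#' @export
conservation_features <- function(profile, position, wt_aa, mut_aa) {
  check_aa(c(wt_aa, mut_aa))
  row <- which(profile$position == position)
  if (length(row) != 1) {
    stop("position ", position, " is not mapped in the profile",
         call. = FALSE)
  }
  c(ic = profile$ic[row],
    pssm_wt = profile[[paste0("pssm_", wt_aa)]][row],
    pssm_mut = profile[[paste0("pssm_", mut_aa)]][row])
}

#' Co-evolution features at the variant site
#'
#' @inheritParams conservation_features
#' @return named vector of the four co-evolution proxy values.
#' @export
coevolution_features <- function(profile, position) {
  row <- which(profile$position == position)
  if (length(row) != 1) {
    stop("position ", position, " is not mapped in the profile",
         call. = FALSE)
  }
  c(is_coevolving = profile$is_coevolving[row],
    max_cor = profile$max_cor[row],
    is_coevolving_grp = profile$is_coevolving_grp[row],
    grp_count = profile$grp_count[row])
}

#' AAindex substitution encodings
#'
#' Per-residue indices are encoded as the difference `value(mut) -
#' value(wt)` (a single scalar per index); substitution matrices and
#' contact potentials contribute their `(wt, mut)` entry, symmetric
#' matrices being read symmetrically.
#'
#' @param table an `aaindex_table`.
#' @param wt_aa,mut_aa residues.
#' @return named vector of 617 values (`aaindex_<accession>` names).
#' @export
aaindex_features <- function(table, wt_aa, mut_aa) {
  check_aa(c(wt_aa, mut_aa))
  idx <- vapply(table$indices, function(v) v[[mut_aa]] - v[[wt_aa]],
                numeric(1))
  mats <- vapply(table$matrices, function(m) {
    v <- m[wt_aa, mut_aa]
    if (is.na(v)) v <- m[mut_aa, wt_aa]
    v
  }, numeric(1))
  out <- c(idx, mats)
  names(out) <- paste0("aaindex_", names(out))
  out
}

#' Substitution-type one-hot encodings
#'
#' A 400-slot block with a single 1 at the (wt, mut) residue pair, and a
#' 36-slot block with a single 1 at the (group(wt), group(mut)) pair of
#' physicochemical groups (hydrophobic V/I/L/F/M/W/Y/C, negatively
#' charged D/E, positively charged R/K/H, conformational G/P, polar
#' N/Q/S, others A/T).
#'
#' @param wt_aa,mut_aa residues.
#' @return named vector of 436 zeros and ones.
#' @export
variation_type_features <- function(wt_aa, mut_aa) {
  check_aa(c(wt_aa, mut_aa))
  grid20 <- expand.grid(mut = AA20, wt = AA20, stringsAsFactors = FALSE)
  v20 <- setNames(numeric(400), paste0("vt_", grid20$wt, grid20$mut))
  v20[paste0("vt_", wt_aa, mut_aa)] <- 1
  g6 <- names(AA_GROUPS6)
  grid6 <- expand.grid(mut = g6, wt = g6, stringsAsFactors = FALSE)
  v6 <- setNames(numeric(36), paste0("vg_", grid6$wt, "_", grid6$mut))
  v6[paste0("vg_", aa_group6(wt_aa), "_", aa_group6(mut_aa))] <- 1
  c(v20, v6)
}

#' Sequence-neighbourhood composition features
#'
#' Counts the residues in a 23-position window centred on the variant
#' site (11 positions on each side, the site itself excluded, truncated
#' at the termini): 20 per-residue counts plus the numbers of nonpolar,
#' polar, charged, positively and negatively charged neighbours.
#'
#' @param sequence reference protein sequence.
#' @param position 1-based variant position.
#' @return named vector of 25 counts.
#' @export
neighborhood_features <- function(sequence, position) {
  chars <- strsplit(sequence, "")[[1]]
  n <- length(chars)
  stopifnot(position >= 1, position <= n)
  win <- setdiff(max(1, position - 11):min(n, position + 11), position)
  neigh <- chars[win]
  counts <- as.numeric(table(factor(neigh, levels = AA20)))
  names(counts) <- paste0("nb_", AA20)
  classes <- vapply(AA_CLASSES5, function(cl) sum(neigh %in% cl), numeric(1))
  names(classes) <- paste0("nbc_", names(AA_CLASSES5))
  c(counts, classes)
}

#' Assemble the full 1106-slot feature vector for one variant
#'
#' @param record one row of a harmonized `variant_table`.
#' @param sequence the reference protein sequence.
#' @param profile the protein's `conservation_profile`.
#' @param table an `aaindex_table`.
#' @param external optional named vector of the 19 external per-protein
#'   descriptors (`external_01` ... `external_19`); when absent those
#'   slots are `NA` and carry a missing-mask for downstream imputation.
#' @param registry the `feature_registry` ordering the output.
#' @return named numeric vector of length 1106 with attribute
#'   `missing_mask` (logical).
#' @export
assemble_features <- function(record, sequence, profile, table,
                              external = NULL,
                              registry = feature_registry(table)) {
  ext <- setNames(rep(NA_real_, 19), sprintf("external_%02d", 1:19))
  if (!is.null(external)) {
    ext[names(external)] <- as.numeric(external)
  }
  vec <- c(condition_features(record),
           conservation_features(profile, record$position, record$wt_aa,
                                 record$mut_aa),
           coevolution_features(profile, record$position),
           aaindex_features(table, record$wt_aa, record$mut_aa),
           variation_type_features(record$wt_aa, record$mut_aa),
           neighborhood_features(sequence, record$position),
           ext)
  if (length(vec) != nrow(registry) ||
      !identical(names(vec), registry$name)) {
    stop("assembled vector does not match the feature registry",
         call. = FALSE)
  }
  attr(vec, "missing_mask") <- is.na(vec)
  vec
}

#' Build a feature table for a set of variants
#'
#' @param records a harmonized `variant_table`.
#' @param sequences named character vector of reference sequences keyed by
#'   `sequence_ref`.
#' @param profiles named list of `conservation_profile`s keyed by
#'   `sequence_ref`.
#' @param table an `aaindex_table`.
#' @param externals optional data.frame of external descriptors with a
#'   `protein_id` column plus `external_01` ... `external_19`.
#' @return numeric matrix (rows = records, columns = registry order) with
#'   `rownames = record_id`.
#' @export
build_feature_table <- function(records, sequences, profiles,
                                table = default_aaindex_table(),
                                externals = NULL) {
  registry <- feature_registry(table)
  out <- matrix(NA_real_, nrow(records), nrow(registry),
                dimnames = list(records$record_id, registry$name))
  for (i in seq_len(nrow(records))) {
    ref <- records$sequence_ref[i]
    ext <- NULL
    if (!is.null(externals)) {
      row <- externals[externals$protein_id == records$protein_id[i], ,
                       drop = FALSE]
      if (nrow(row) == 1) {
        ext <- unlist(row[sprintf("external_%02d", 1:19)])
        names(ext) <- sprintf("external_%02d", 1:19)
      }
    }
    out[i, ] <- assemble_features(records[i, , drop = FALSE],
                                  sequences[[ref]], profiles[[ref]],
                                  table, ext, registry)
  }
  out
}

#' Write a feature table as TSV with registry names as header
#'
#' @param x feature matrix from [build_feature_table()].
#' @param path output path.
#' @export
write_feature_table <- function(x, path) {
  df <- data.frame(record_id = rownames(x), x, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
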