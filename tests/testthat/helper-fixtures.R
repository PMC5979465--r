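# Shared helpers for building tiny in-code fixtures.

# A minimal harmonizable variant data.frame (already in the parsed layout).
toy_records <- function(n = 3) {
  df <- data.frame(
    record_id = sprintf("V%02d", seq_len(n)),
    protein_id = "P001", sequence_ref = "P001",
    wt_aa = rep(c("A", "K", "V"), length.out = n),
    position = rep(c(2, 5, 9), length.out = n),
    mut_aa = rep(c("V", "R", "A"), length.out = n),
    ddg = rep(c(1.2, -2.0, 0.2), length.out = n),
    ddg_unit = "kcal/mol", temperature = 25, ph = 7,
    salt_molar = 0.1, method = "DSC", pdb_ref = NA,
    background_variants = NA, state_flag = "folded",
    stringsAsFactors = FALSE)
  class(df) <- c("variant_table", "data.frame")
  df
}

write_records_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# An MSA whose column content is given explicitly: `cols` is a list of
# character vectors (one per column), all the same depth.
msa_from_columns <- function(cols, ref_index = 1L) {
  mat <- do.call(cbind, cols)
  new_msa(apply(mat, 1, paste, collapse = ""), ref_index)
}

# Two-fold split helper for selection/model tests.
even_folds <- function(n, k = 2) {
  lapply(seq_len(k), function(f) {
    test <- seq(f, n, by = k)
    list(train = setdiff(seq_len(n), test), test = test)
  })
}
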