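#' @importFrom stats median setNames predict rnorm runif
#' @importFrom utils read.delim write.table head
NULL

VARIANT_COLUMNS <- c("record_id", "protein_id", "sequence_ref", "wt_aa",
                     "position", "mut_aa", "ddg", "ddg_unit", "temperature",
                     "ph", "salt_molar", "method", "pdb_ref",
                     "background_variants", "state_flag")

MANDATORY_COLUMNS <- c("record_id", "protein_id", "sequence_ref", "wt_aa",
                       "position", "mut_aa", "ddg", "ddg_unit", "temperature",
                       "ph", "method", "state_flag")

METHOD_LEVELS <- c("DSC", "thermal_other", "chemical_denaturation", "other")
STATE_LEVELS <- c("folded", "unfolded", "stage_partial", "stage_total")

#' Curation configuration
#'
#' Thresholds and preferences applied by [apply_curation()]. The defaults
#' encode the curation window used to assemble the benchmark: measurements
#' in pH 5--9 and below 0.2 M salt are preferred, values within +-0.5
#' kcal/mol are treated as having no effect on stability, and chains
#' shorter than 30 residues are not considered true folded proteins.
#'
#' @param ph_min,ph_max preferred pH window.
#' @param salt_max_molar maximum preferred salt concentration, mol/L.
#' @param neutral_halfwidth half-width of the neutral ddG band, kcal/mol.
#' @param min_protein_length minimum chain length counted as a protein.
#' @param method_preference ordered preference over measurement methods,
#'   best first.
#' @return an object of class `curation_config`.
#' @export
curation_config <- function(ph_min = 5, ph_max = 9, salt_max_molar = 0.2,
                            neutral_halfwidth = 0.5, min_protein_length = 30,
                            method_preference = METHOD_LEVELS) {
  stopifnot(ph_min < ph_max, neutral_halfwidth > 0, min_protein_length >= 1)
  structure(list(ph_min = ph_min, ph_max = ph_max,
                 salt_max_molar = salt_max_molar,
                 neutral_halfwidth = neutral_halfwidth,
                 min_protein_length = min_protein_length,
                 method_preference = method_preference),
            class = "curation_config")
}

#' Parse tab-separated variant records
#'
#' Reads a TSV file of stability measurements (one amino acid substitution
#' with its experimental conditions per row) into a validated variant
#' table. Rows that fail validation (bad amino-acid code, identical
#' wild-type and substituting residue, non-positive position, non-finite
#' ddG) are reported in the `errors` element rather than silently dropped.
#'
#' @param path path to a UTF-8 TSV file with a header row naming at least
#'   the mandatory columns (`record_id`, `protein_id`, `sequence_ref`,
#'   `wt_aa`, `position`, `mut_aa`, `ddg`, `ddg_unit`, `temperature`,
#'   `ph`, `method`, `state_flag`). Optional columns: `salt_molar`,
#'   `pdb_ref`, `background_variants` (semicolon-separated tokens such as
#'   `C54T`), `ddg_sign` (`stabilizing_positive` or
#'   `destabilizing_positive`).
#' @return a list with `records` (data.frame of valid rows, class
#'   `variant_table`) and `errors` (data.frame with `row`, `record_id`,
#'   `reason`).
#' @export
parse_variant_records <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE,
                    na.strings = c("NA", ""))
  missing_cols <- setdiff(MANDATORY_COLUMNS, names(raw))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  for (opt in c("salt_molar", "pdb_ref", "background_variants", "ddg_sign")) {
    if (!opt %in% names(raw)) raw[[opt]] <- NA
  }
  raw$position <- suppressWarnings(as.integer(raw$position))
  raw$ddg <- suppressWarnings(as.numeric(raw$ddg))
  raw$temperature <- suppressWarnings(as.numeric(raw$temperature))
  raw$ph <- suppressWarnings(as.numeric(raw$ph))
  raw$salt_molar <- suppressWarnings(as.numeric(raw$salt_molar))

  reasons <- character(nrow(raw))
  flag <- function(idx, why) {
    reasons[idx & reasons == ""] <<- why
  }
  flag(!raw$wt_aa %in% AA20 | !raw$mut_aa %in% AA20, "bad_amino_acid_code")
  flag(raw$wt_aa == raw$mut_aa, "wt_equals_mut")
  flag(is.na(raw$position) | raw$position < 1, "bad_position")
  flag(is.na(raw$ddg) | !is.finite(raw$ddg), "bad_ddg")
  flag(!raw$ddg_unit %in% c("kcal/mol", "kJ/mol"), "unknown_unit")
  flag(!raw$method %in% METHOD_LEVELS, "unknown_method")
  flag(!raw$state_flag %in% STATE_LEVELS, "unknown_state_flag")

  bad <- reasons != ""
  errors <- data.frame(row = which(bad),
                       record_id = as.character(raw$record_id[bad]),
                       reason = reasons[bad], stringsAsFactors = FALSE)
  records <- raw[!bad, , drop = FALSE]
  rownames(records) <- NULL
  records$record_id <- as.character(records$record_id)
  class(records) <- c("variant_table", "data.frame")
  list(records = records, errors = errors)
}

#' Harmonize units and sign conventions of variant records
#'
#' Converts ddG values reported in kJ/mol to kcal/mol (dividing by 4.184),
#' interprets temperatures above 150 as Kelvin readings and shifts them by
#' -273.15 to Celsius, and flips the sign of records declared to use the
#' destabilizing-positive convention so that a positive ddG always means a
#' stabilizing substitution. Idempotent: applying it twice equals applying
#' it once.
#'
#' @param records a `variant_table`.
#' @return the records with `ddg` in kcal/mol, `temperature` in Celsius,
#'   a unified sign convention, and a logical `harmonized_change` column
#'   marking rows that were altered.
#' @export
harmonize_units <- function(records) {
  stopifnot(is.data.frame(records))
  unknown <- !records$ddg_unit %in% c("kcal/mol", "kJ/mol")
  if (any(unknown)) {
    stop("unknown ddg unit token: ",
         paste(unique(records$ddg_unit[unknown]), collapse = ", "),
         call. = FALSE)
  }
  changed <- logical(nrow(records))

  kj <- records$ddg_unit == "kJ/mol"
  records$ddg[kj] <- records$ddg[kj] / KJ_PER_KCAL
  records$ddg_unit[kj] <- "kcal/mol"
  changed <- changed | kj

  kelvin <- !is.na(records$temperature) &
    records$temperature > KELVIN_SUSPECT_C
  records$temperature[kelvin] <- records$temperature[kelvin] - KELVIN_OFFSET
  changed <- changed | kelvin

  if ("ddg_sign" %in% names(records)) {
    flip <- !is.na(records$ddg_sign) &
      records$ddg_sign == "destabilizing_positive"
    records$ddg[flip] <- -records$ddg[flip]
    records$ddg_sign[flip] <- "stabilizing_positive"
    changed <- changed | flip
  }

  out_of_range <- !is.na(records$temperature) &
    (records$temperature < -10 | records$temperature > 150)
  if (any(out_of_range)) {
    warning(sum(out_of_range),
            " record(s) with temperature outside [-10, 150] degC after ",
            "harmonization")
  }
  if ("harmonized_change" %in% names(records)) {
    records$harmonized_change <- records$harmonized_change | changed
  } else {
    records$harmonized_change <- changed
  }
  records
}

#' Assign the three-class stability label
#'
#' Labels a harmonized ddG (kcal/mol, positive = stabilizing):
#' `increase` when ddG exceeds the neutral half-width, `decrease` when it
#' falls below its negative, and `no_effect` inside the closed band
#' `[-halfwidth, +halfwidth]` (boundary values are neutral).
#'
#' @param ddg numeric vector of harmonized ddG values, kcal/mol.
#' @param neutral_halfwidth half-width of the neutral band, kcal/mol.
#' @return factor with levels `increase`, `no_effect`, `decrease`.
#' @export
label_stability <- function(ddg, neutral_halfwidth = 0.5) {
  stopifnot(all(is.finite(ddg)), neutral_halfwidth > 0)
  out <- rep("no_effect", length(ddg))
  out[ddg > neutral_halfwidth] <- "increase"
  out[ddg < -neutral_halfwidth] <- "decrease"
  factor(out, levels = STABILITY_CLASSES)
}

parse_background_tokens <- function(spec) {
  if (is.null(spec) || length(spec) == 0 || is.na(spec) || !nzchar(spec)) {
    return(data.frame(wt = character(), position = integer(),
                      mut = character(), stringsAsFactors = FALSE))
  }
  toks <- strsplit(spec, ";", fixed = TRUE)[[1]]
  toks <- trimws(toks[nzchar(trimws(toks))])
  m <- regmatches(toks, regexec("^([A-Z])([0-9]+)([A-Z])$", toks))
  bad <- vapply(m, length, integer(1)) != 4
  if (any(bad)) {
    stop("malformed background variant token: ",
         paste(toks[bad], collapse = ", "), call. = FALSE)
  }
  data.frame(wt = vapply(m, `[`, "", 2),
             position = as.integer(vapply(m, `[`, "", 3)),
             mut = vapply(m, `[`, "", 4), stringsAsFactors = FALSE)
}

apply_background <- function(sequence, background) {
  if (nrow(background) == 0) return(sequence)
  chars <- strsplit(sequence, "")[[1]]
  for (i in seq_len(nrow(background))) {
    p <- background$position[i]
    if (p > length(chars)) {
      stop("background variant position ", p, " beyond sequence length",
           call. = FALSE)
    }
    chars[p] <- background$mut[i]
  }
  paste(chars, collapse = "")
}

#' Validate a variant against its reference sequence
#'
#' Applies the record's background variants (e.g. the C54T/C97A changes of
#' a pseudo-wild-type construct) to the reference sequence, then checks
#' that the residue at the 1-based variant position equals the declared
#' wild-type residue. On mismatch, nearby offsets (+-5) are probed to
#' distinguish a numbering shift from an outright sequence mismatch.
#'
#' @param sequence reference protein sequence (one-letter codes).
#' @param wt_aa,position declared wild-type residue and 1-based position.
#' @param background_variants background specification string
#'   (semicolon-separated tokens like `"C54T;C97A"`), or `NA`.
#' @return list with `ok` (logical) and `reason` (`"match"`,
#'   `"out_of_range"`, `"shift_candidate offset <d>"`, or `"mismatch"`).
#' @export
validate_sequence <- function(sequence, wt_aa, position,
                              background_variants = NA) {
  stopifnot(nzchar(sequence))
  seq2 <- apply_background(sequence,
                           parse_background_tokens(background_variants))
  chars <- strsplit(seq2, "")[[1]]
  n <- length(chars)
  if (position < 1 || position > n) {
    return(list(ok = FALSE, reason = "out_of_range"))
  }
  if (chars[position] == wt_aa) return(list(ok = TRUE, reason = "match"))
  for (off in c(1, -1, 2, -2, 3, -3, 4, -4, 5, -5)) {
    p <- position + off
    if (p >= 1 && p <= n && chars[p] == wt_aa) {
      return(list(ok = FALSE,
                  reason = sprintf("shift_candidate offset %+d", off)))
    }
  }
  list(ok = FALSE, reason = "mismatch")
}

variant_key <- function(records) {
  paste(records$protein_id, records$wt_aa, records$position,
        records$mut_aa, sep = "|")
}

duplicate_key <- function(records) {
  paste(variant_key(records), signif(records$ddg, 10),
        signif(records$temperature, 10), signif(records$ph, 10), sep = "|")
}

method_rank <- function(method, preference) {
  r <- match(method, preference)
  r[is.na(r)] <- length(preference) + 1L
  r
}

#' Select a single representative measurement for one variant
#'
#' Among several measurements of the same substitution, picks the one with
#' the preferred method (calorimetric > other thermal > chemical
#' denaturation > other), breaking ties by pH closest to 7, then lowest
#' salt concentration (unknown salt sorts last), then record_id order.
#'
#' @param records a `variant_table` whose rows all describe the same
#'   (protein, wt, position, mut) substitution.
#' @param config a [curation_config()].
#' @return the single chosen row.
#' @export
select_representative <- function(records, config = curation_config()) {
  if (nrow(records) == 0) stop("no records to select from", call. = FALSE)
  if (length(unique(variant_key(records))) != 1) {
    stop("select_representative expects records of a single variant",
         call. = FALSE)
  }
  salt <- records$salt_molar
  salt[is.na(salt)] <- Inf
  ord <- order(method_rank(records$method, config$method_preference),
               abs(records$ph - 7), salt, records$record_id)
  records[ord[1], , drop = FALSE]
}

#' Curate a harmonized variant table
#'
#' Applies the mechanical curation rules in a fixed order and records
#' every exclusion with a machine-readable reason code so the cleaning is
#' auditable: (1) measurements on unfolded proteins and values for partial
#' stages of multi-step denaturation pathways are always rejected;
#' (2) variants in chains shorter than the minimum protein length are
#' rejected; (3) records whose declared wild-type residue does not match
#' the (background-corrected) reference sequence are rejected;
#' (4) measurements at out-of-window pH or salt are rejected only when an
#' in-window measurement of the same variant exists; (5) exact duplicates
#' are collapsed; (6) remaining multiplicity is resolved by
#' [select_representative()], superseded records being rejected with
#' reason `non_preferred_superseded`.
#'
#' @param records a harmonized `variant_table`.
#' @param sequences optional named character vector of reference sequences
#'   keyed by `sequence_ref`; enables the short-peptide and
#'   sequence-mismatch checks.
#' @param config a [curation_config()].
#' @return list with `curated` (kept rows plus a `label` column) and
#'   `report` (data.frame `record_id`, `status`, `reason`, `detail`;
#'   every input record appears exactly once).
#' @export
apply_curation <- function(records, sequences = NULL,
                           config = curation_config()) {
  stopifnot(is.data.frame(records))
  n <- nrow(records)
  status <- rep("kept", n)
  reason <- rep("", n)
  detail <- rep("", n)
  reject <- function(idx, why, what = "") {
    hit <- idx & status == "kept"
    status[hit] <<- "rejected"
    reason[hit] <<- why
    detail[hit] <<- what
  }

  reject(records$state_flag == "unfolded", "unfolded_protein")
  reject(records$state_flag == "stage_partial", "stage_value")

  if (!is.null(sequences)) {
    seq_len_of <- nchar(sequences)[records$sequence_ref]
    known <- !is.na(seq_len_of)
    reject(known & seq_len_of < config$min_protein_length, "short_peptide")
    for (i in which(status == "kept" & known)) {
      v <- validate_sequence(sequences[[records$sequence_ref[i]]],
                             records$wt_aa[i], records$position[i],
                             records$background_variants[i])
      if (!v$ok) reject(seq_len(n) == i, "sequence_mismatch", v$reason)
    }
  }

  in_window <- function(i) {
    ph_ok <- records$ph[i] >= config$ph_min & records$ph[i] <= config$ph_max
    salt_ok <- is.na(records$salt_molar[i]) |
      records$salt_molar[i] <= config$salt_max_molar
    ph_ok & salt_ok
  }
  keys <- variant_key(records)
  for (k in unique(keys[status == "kept"])) {
    idx <- which(keys == k & status == "kept")
    ok <- vapply(idx, in_window, logical(1))
    if (any(ok) && any(!ok)) {
      bad <- idx[!ok]
      ph_bad <- records$ph[bad] < config$ph_min |
        records$ph[bad] > config$ph_max
      reject(seq_len(n) %in% bad[ph_bad], "out_of_range_ph_superseded")
      reject(seq_len(n) %in% bad[!ph_bad], "out_of_range_salt_superseded")
    }
  }

  dkeys <- duplicate_key(records)
  for (k in unique(dkeys[status == "kept"])) {
    idx <- which(dkeys == k & status == "kept")
    if (length(idx) > 1) {
      keep <- idx[order(records$record_id[idx])][1]
      reject(seq_len(n) %in% setdiff(idx, keep), "duplicate",
             records$record_id[keep])
    }
  }

  for (k in unique(keys[status == "kept"])) {
    idx <- which(keys == k & status == "kept")
    if (length(idx) > 1) {
      rep_row <- select_representative(records[idx, , drop = FALSE], config)
      keep <- idx[records$record_id[idx] == rep_row$record_id[1]][1]
      reject(seq_len(n) %in% setdiff(idx, keep), "non_preferred_superseded",
             records$record_id[keep])
    }
  }

  curated <- records[status == "kept", , drop = FALSE]
  curated$label <- label_stability(curated$ddg, config$neutral_halfwidth)
  rownames(curated) <- NULL
  class(curated) <- c("variant_table", "data.frame")
  report <- data.frame(record_id = records$record_id, status = status,
                       reason = reason, detail = detail,
                       stringsAsFactors = FALSE)
  list(curated = curated, report = report)
}

#' Augment a variant table with reverse variants
#'
#' For every record, emits the mirrored substitution: wild-type and
#' substituting residues swapped, ddG negated, and (when sequences are
#' supplied) the reference sequence carrying the forward substitution so
#' the mirrored record is measured against the mutated background.
#' Originals are retained; mirrored records carry `reversed = TRUE` and a
#' `_rev`-suffixed record id.
#'
#' @param records a `variant_table`.
#' @param sequences optional named character vector of reference
#'   sequences; mutated sequences are added under
#'   `<sequence_ref>:<wt><pos><mut>` keys.
#' @return list with `records` (2n rows) and `sequences` (possibly
#'   extended).
#' @export
make_reverse_variants <- function(records, sequences = NULL) {
  rev <- records
  rev$record_id <- paste0(records$record_id, "_rev")
  rev$wt_aa <- records$mut_aa
  rev$mut_aa <- records$wt_aa
  rev$ddg <- -records$ddg
  if (!is.null(sequences)) {
    new_ref <- paste0(records$sequence_ref, ":", records$wt_aa,
                      records$position, records$mut_aa)
    for (i in seq_len(nrow(records))) {
      ref <- records$sequence_ref[i]
      if (!new_ref[i] %in% names(sequences) && ref %in% names(sequences)) {
        chars <- strsplit(sequences[[ref]], "")[[1]]
        chars[records$position[i]] <- records$mut_aa[i]
        sequences[[new_ref[i]]] <- paste(chars, collapse = "")
      }
    }
    rev$sequence_ref <- new_ref
  }
  records$reversed <- FALSE
  rev$reversed <- TRUE
  out <- rbind(records, rev)
  rownames(out) <- NULL
  class(out) <- c("variant_table", "data.frame")
  list(records = out, sequences = sequences)
}

#' Write a curated dataset and its rejection report
#'
#' @param curation result of [apply_curation()].
#' @param dataset_path,report_path output TSV paths.
#' @return invisibly, the paths.
#' @export
write_curation <- function(curation, dataset_path, report_path) {
  write.table(curation$curated, dataset_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(curation$report, report_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(c(dataset_path, report_path))
}
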