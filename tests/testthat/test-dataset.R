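test_that("parsing reads valid rows and reports bad rows without dropping them silently", {
  df <- toy_records(3)
  df$ddg_unit[2] <- "kJ/mol"
  path <- write_records_tsv(df)
  parsed <- parse_variant_records(path)
  expect_equal(nrow(parsed$records), 3)
  expect_equal(nrow(parsed$errors), 0)
  expect_equal(sum(parsed$records$ddg_unit == "kJ/mol"), 1)

  bad <- toy_records(4)
  bad$position[2] <- 0
  bad$wt_aa[3] <- "B"
  parsed2 <- parse_variant_records(write_records_tsv(bad))
  expect_equal(nrow(parsed2$records), 2)
  expect_setequal(parsed2$errors$reason,
                  c("bad_position", "bad_amino_acid_code"))
})

test_that("a missing mandatory column is a hard error naming the column", {
  df <- toy_records(2)
  df$ph <- NULL
  expect_error(parse_variant_records(write_records_tsv(df)), "ph")
})

test_that("unit and temperature harmonization follows the stated conversions", {
  df <- toy_records(3)
  df$ddg <- c(4.184, -8.368, 1)
  df$ddg_unit <- c("kJ/mol", "kJ/mol", "kcal/mol")
  df$temperature <- c(298.15, 25, 25)
  h <- harmonize_units(df)
  expect_equal(h$ddg, c(1.0, -2.0, 1))
  expect_equal(h$temperature, c(25, 25, 25))
  expect_true(all(h$ddg_unit == "kcal/mol"))
  expect_equal(h$harmonized_change, c(TRUE, TRUE, FALSE))

  df$ddg_unit[1] <- "cal/mol"
  expect_error(harmonize_units(df), "unknown ddg unit")
})

test_that("harmonization is idempotent and flips declared sign conventions", {
  df <- toy_records(2)
  df$ddg <- c(8.368, 2)
  df$ddg_unit <- c("kJ/mol", "kcal/mol")
  df$ddg_sign <- c("stabilizing_positive", "destabilizing_positive")
  once <- harmonize_units(df)
  twice <- harmonize_units(once)
  expect_equal(once$ddg, c(2, -2))
  expect_identical(once$ddg, twice$ddg)
  expect_identical(once$temperature, twice$temperature)
})

test_that("stability labelling partitions the line with a closed neutral band", {
  expect_equal(as.character(label_stability(c(0.3, -2.0, 0.5, -0.5, 0.51))),
               c("no_effect", "decrease", "no_effect", "no_effect",
                 "increase"))
  # every finite value gets exactly one label; mirror property
  set.seed(1)
  x <- runif(200, -20, 20)
  lab <- label_stability(x)
  expect_false(anyNA(lab))
  big <- abs(x) > 0.5
  mirror <- label_stability(-x)
  expect_true(all((lab[big] == "increase") == (mirror[big] == "decrease")))
})

test_that("sequence validation applies backgrounds and diagnoses shifts", {
  expect_true(validate_sequence("MKV", "K", 2)$ok)
  v <- validate_sequence("MKV", "V", 2)
  expect_false(v$ok)
  expect_equal(v$reason, "shift_candidate offset +1")
  expect_equal(validate_sequence("MKV", "K", 9)$reason, "out_of_range")
  # background C54T applied before checking position 54
  seq54 <- paste(c(rep("A", 53), "C", rep("G", 10)), collapse = "")
  expect_false(validate_sequence(seq54, "T", 54)$ok)
  expect_true(validate_sequence(seq54, "T", 54, "C54T")$ok)
})

test_that("out-of-window pH measurements are rejected only when superseded", {
  df <- toy_records(2)
  df$record_id <- c("a", "b")
  df$wt_aa <- "A"; df$mut_aa <- "V"; df$position <- 2
  df$ph <- c(3.0, 7.0)
  df$ddg <- c(1.0, 1.1)
  cur <- apply_curation(df)
  rep <- cur$report
  expect_equal(rep$status[rep$record_id == "a"], "rejected")
  expect_equal(rep$reason[rep$record_id == "a"], "out_of_range_ph_superseded")
  expect_equal(rep$status[rep$record_id == "b"], "kept")

  # a lone pH 4 measurement with no alternative is kept
  solo <- toy_records(1)
  solo$ph <- 4.0
  cur2 <- apply_curation(solo)
  expect_equal(cur2$report$status, "kept")
})

test_that("curation never invents records and reports each input exactly once", {
  df <- toy_records(3)
  cur <- apply_curation(df)
  expect_setequal(cur$report$record_id, df$record_id)
  expect_equal(nrow(cur$report), nrow(df))
  expect_true(all(cur$curated$record_id %in% df$record_id))
})

test_that("representative selection prefers calorimetry, then pH near 7, then low salt", {
  df <- toy_records(2)
  df$wt_aa <- "A"; df$mut_aa <- "V"; df$position <- 2
  df$method <- c("chemical_denaturation", "DSC")
  df$ph <- c(7, 6)
  expect_equal(select_representative(df)$record_id, "V02")

  df2 <- df
  df2$method <- "thermal_other"
  df2$ph <- c(8.5, 6.5)
  expect_equal(select_representative(df2)$record_id, "V02")

  df3 <- df
  df3$method <- "DSC"; df3$ph <- 7; df3$salt_molar <- 0.1
  expect_equal(select_representative(df3)$record_id, "V01")
  expect_error(select_representative(df[0, ]), "no records")
})

test_that("reverse variants mirror the substitution and invert on re-application", {
  df <- toy_records(3)
  seqs <- c(P001 = "MAKWLAYVQV")
  out <- make_reverse_variants(df, seqs)
  expect_equal(nrow(out$records), 2 * nrow(df))
  rev <- out$records[out$records$reversed, ]
  expect_equal(rev$wt_aa, df$mut_aa)
  expect_equal(rev$mut_aa, df$wt_aa)
  expect_equal(rev$ddg, -df$ddg)
  # a neutral record stays neutral in mirror form
  expect_equal(as.character(label_stability(rev$ddg[3])), "no_effect")
  # mirrored sequence carries the forward substitution
  expect_equal(substr(out$sequences[["P001:A2V"]], 2, 2), "V")
  # mirroring the mirrors restores the original triples
  back <- make_reverse_variants(rev)$records
  back2 <- back[back$reversed, ]
  expect_equal(back2$wt_aa, df$wt_aa)
  expect_equal(back2$mut_aa, df$mut_aa)
  expect_equal(back2$ddg, df$ddg)
})

test_that("duplicates collapse deterministically and multiplicity resolves to one row", {
  df <- toy_records(1)
  dup <- df; dup$record_id <- "V01_dup"
  alt <- df; alt$record_id <- "V00"; alt$ddg <- df$ddg + 0.3
  alt$method <- "chemical_denaturation"
  all3 <- rbind(df, dup, alt)
  class(all3) <- c("variant_table", "data.frame")
  cur <- apply_curation(all3)
  expect_equal(cur$curated$record_id, "V01")
  rep <- cur$report
  expect_equal(rep$reason[rep$record_id == "V01_dup"], "duplicate")
  expect_equal(rep$reason[rep$record_id == "V00"],
               "non_preferred_superseded")
})
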