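tab <- default_aaindex_table()
reg <- feature_registry(tab)

test_that("the registry census sums to 1106 with the stated family sizes", {
  expect_equal(nrow(reg), 1106)
  fam <- table(reg$family)
  expect_equal(as.integer(fam[c("condition", "conservation", "coevolution",
                                "aaindex", "vartype20x20", "vartype6x6",
                                "neighborhood_counts",
                                "neighborhood_classes",
                                "external_protein")]),
               c(2L, 3L, 4L, 617L, 400L, 36L, 20L, 5L, 19L))
  expect_false(anyDuplicated(reg$name) > 0)
  # order stable across constructions
  expect_identical(reg$name, feature_registry(tab)$name)
})

test_that("the AAindex flat-file parser filters incomplete entries", {
  path <- system.file("extdata", "synthetic_aaindex_example.txt",
                      package = "protstab")
  entries <- parse_aaindex(path)
  expect_equal(length(entries), 3)
  expect_equal(vapply(entries, `[[`, "", "accession"),
               c("SYNI0001", "SYNI0002", "SYNM0001"))
  expect_equal(vapply(entries, `[[`, TRUE, "complete"),
               c(TRUE, FALSE, TRUE))
  tab2 <- aaindex_table(entries)
  expect_equal(tab2$n_features, 2)
  # mirrored lower triangle is symmetric
  m <- tab2$matrices$SYNM0001
  expect_equal(m, t(m))
})

test_that("condition features copy harmonized temperature and pH verbatim", {
  rec <- toy_records(1)
  expect_equal(condition_features(rec), c(temperature_c = 25, ph = 7))
  k <- rec; k$temperature <- 298.15
  h <- harmonize_units(k)
  expect_equal(condition_features(h)[["temperature_c"]], 25)
  rec$ph <- NA
  expect_error(condition_features(rec), "pH")
})

test_that("conservation features reproduce the toy-column hand computation", {
  msa <- msa_from_columns(list(c("A", "A", "A", "V"), rep("W", 4)))
  prof <- conservation_profile(msa)
  f <- conservation_features(prof, 1, "A", "V")
  expect_equal(f[["ic"]], log2(20) + 0.75 * log2(0.75) + 0.25 * log2(0.25),
               tolerance = 1e-10)
  expect_gt(f[["pssm_wt"]], f[["pssm_mut"]])
  # fully conserved wt column: maximal IC, wt score maximal
  f2 <- conservation_features(prof, 2, "W", "A")
  expect_equal(f2[["ic"]], log2(20), tolerance = 1e-10)
  expect_equal(f2[["pssm_wt"]], max(prof[2, paste0("pssm_", AA20)]))
  expect_error(conservation_features(prof, 7, "A", "V"), "not mapped")
})

test_that("per-residue AAindex encoding is mut minus wt with the expected sign", {
  f <- aaindex_features(tab, "A", "A")
  idx_names <- paste0("aaindex_", names(tab$indices))
  expect_true(all(f[idx_names] == 0))
  # hydropathy (Kyte-Doolittle): I -> D is a strongly negative difference
  kd <- f <- aaindex_features(tab, "I", "D")
  expect_lt(kd[["aaindex_KYTJ820101"]], 0)
  expect_equal(kd[["aaindex_KYTJ820101"]], -3.5 - 4.5)
  expect_equal(length(f), 617)
})

test_that("substitution-type one-hot blocks each sum to exactly one", {
  v <- variation_type_features("A", "V")
  expect_equal(sum(v[startsWith(names(v), "vt_")]), 1)
  expect_equal(sum(v[startsWith(names(v), "vg_")]), 1)
  expect_equal(v[["vt_AV"]], 1)
  expect_equal(v[["vg_other_hydrophobic"]], 1)
  v2 <- variation_type_features("D", "E")
  expect_equal(v2[["vg_negative_negative"]], 1)
  expect_error(variation_type_features("A", "B"), "non-canonical")
})

test_that("neighbourhood counts cover 11 positions each side, excluding the site", {
  polyA <- strrep("A", 23)
  f <- neighborhood_features(polyA, 12)
  expect_equal(f[["nb_A"]], 22)
  expect_equal(sum(f[paste0("nb_", AA20)]), 22)
  expect_equal(f[["nbc_nonpolar"]], 22)
  # terminal truncation: site 1 sees positions 2..12 only
  f2 <- neighborhood_features(polyA, 1)
  expect_equal(sum(f2[paste0("nb_", AA20)]), 11)
  # hand tally on a mixed sequence
  s <- "MKVLDERTAGYWSNQPHCIF"
  f3 <- neighborhood_features(s, 10)
  neigh <- strsplit("MKVLDERTA YWSNQPHCIF", "")[[1]]
  neigh <- neigh[neigh != " "]
  expect_equal(f3[["nb_K"]], sum(neigh == "K"))
  expect_equal(f3[["nbc_negative"]], sum(neigh %in% c("D", "E")))
  expect_equal(f3[["nbc_charged"]],
               sum(neigh %in% c("D", "E", "K", "R")))
})

test_that("assembly is a deterministic pure function with the registry layout", {
  spec <- fixture_spec(n_proteins = 1, variants_per_protein = 2,
                       protein_length = 40, seed = 13)
  corp <- generate_variant_corpus(spec)
  rec <- harmonize_units(corp$records)[1, ]
  msa <- generate_toy_msa(depth = 12, length = 40, seed = 14)
  msa$sequences[1] <- corp$sequences[[1]]
  prof <- conservation_profile(msa)
  v1 <- assemble_features(rec, corp$sequences[[1]], prof, tab)
  v2 <- assemble_features(rec, corp$sequences[[1]], prof, tab)
  expect_identical(as.numeric(v1), as.numeric(v2))
  expect_equal(length(v1), 1106)
  expect_identical(names(v1), reg$name)
  # without externals: 19 masked slots
  expect_equal(sum(attr(v1, "missing_mask")), 19)
  expect_true(all(names(v1)[attr(v1, "missing_mask")] ==
                    sprintf("external_%02d", 1:19)))
  # with externals supplied nothing is masked
  ext <- setNames(rnorm(19), sprintf("external_%02d", 1:19))
  v3 <- assemble_features(rec, corp$sequences[[1]], prof, tab, ext)
  expect_equal(sum(attr(v3, "missing_mask")), 0)
})
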