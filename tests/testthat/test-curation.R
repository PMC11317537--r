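test_that("completeness filter drops records missing any required field", {
  recs <- make_records(
    make_record(),                       # complete
    make_record(ph = NA),
    make_record(ec_number = NA),
    make_record(sequence = ""),
    make_record(unit = NA),
    make_record(organism = NA),
    make_record(temperature = NA),
    make_record(), make_record(), make_record())
  res <- drop_incomplete(recs)
  expect_equal(nrow(res$kept), 4)
  expect_equal(nrow(res$dropped), 6)
  expect_true(all(res$dropped$reason == "incomplete"))
})

test_that("structural filter enforces heavy-atom range and no fragments", {
  recs <- make_records(
    make_record(substrate_smiles = "CCO"),           # 3 heavy atoms
    make_record(substrate_smiles = "O"),             # 1 heavy atom
    make_record(substrate_smiles = "CC"),            # 2: boundary, dropped
    make_record(substrate_smiles = "CCO.O"),         # fragment dot
    make_record(substrate_smiles = strrep("C", 129)),# > 128
    make_record(substrate_smiles = strrep("C", 128)),# boundary, kept
    make_record(substrate_smiles = "C(#Q"))          # unparseable
  res <- filter_structure(recs)
  expect_equal(res$kept$substrate_smiles, c("CCO", strrep("C", 128)))
  expect_setequal(res$dropped$reason,
                  c("heavy_atoms_out_of_range", "fragment_smiles",
                    "unparseable_smiles"))
  expect_equal(sum(res$dropped$reason == "heavy_atoms_out_of_range"), 3)
})

test_that("heavy atom counting ignores hydrogens", {
  expect_equal(heavy_atom_count(c("CCO", "O", "CC(C)N", "[H]O[H]")),
               c(3L, 1L, 4L, 1L))
  expect_true(is.na(heavy_atom_count("notasmiles(")))
})

test_that("value filter keeps strictly positive values", {
  recs <- make_records(make_record(value = -1), make_record(value = 0),
                       make_record(value = 1e-6), make_record(value = 3))
  res <- filter_values(recs)
  expect_equal(res$kept$value, c(1e-6, 3))
  expect_true(all(res$dropped$reason == "nonpositive_value"))
})

test_that("SMILES canonicalization merges equivalent encodings", {
  expect_equal(canonicalize_smiles("OCC"), canonicalize_smiles("CCO"))
  expect_equal(canonicalize_smiles("c1ccccc1"),
               canonicalize_smiles("C1=CC=CC=C1"))
  can <- canonicalize_smiles("N(C)C(=O)O")
  expect_identical(canonicalize_smiles(can), can)  # idempotent
  expect_error(canonicalize_smiles("C(#Q"), "unparseable")
  expect_true(is.na(canonicalize_smiles("C(#Q", on_error = "na")))
})

test_that("mutation codes are applied at 1-based positions with checks", {
  expect_equal(apply_mutations("MKT", "K2A"), "MAT")
  expect_equal(apply_mutations("MKT", c("M1V", "T3S")), "VKS")
  expect_equal(apply_mutations("MKT", "M1V;T3S"), "VKS")  # packed form
  expect_equal(apply_mutations("MKT", character(0)), "MKT")
  expect_error(apply_mutations("MKT", "A2V"), "position 2 holds K")
  expect_error(apply_mutations("MKT", "K9A"), "out of range")
  expect_error(apply_mutations("MKT", "K2"), "malformed")
})

test_that("aggregation keeps max kcat and min Km per assay key", {
  base <- make_record()
  kcat_group <- make_records(
    make_record(value = 1), make_record(value = 5), make_record(value = 3))
  kcat_group$canonical_smiles <- "CCO"
  res <- dedup_and_aggregate(kcat_group)
  expect_equal(nrow(res$entries), 1)
  expect_equal(res$entries$value, 5)
  expect_equal(res$n_aggregated, 2)

  km_group <- make_records(
    make_record(param_kind = "km", value = 2, unit = "mM"),
    make_record(param_kind = "km", value = 0.5, unit = "mM"))
  km_group$canonical_smiles <- "CCO"
  res2 <- dedup_and_aggregate(km_group)
  expect_equal(res2$entries$value, 0.5)

  # byte-identical repeats collapse as duplicates, not aggregation
  dup_group <- make_records(make_record(value = 2), make_record(value = 2))
  dup_group$canonical_smiles <- "CCO"
  res3 <- dedup_and_aggregate(dup_group)
  expect_equal(res3$n_duplicate, 1)
  expect_equal(res3$n_aggregated, 0)

  # singleton group passes through unchanged
  single <- make_records(make_record(value = 7))
  single$canonical_smiles <- "CCO"
  expect_equal(dedup_and_aggregate(single)$entries$value, 7)
})

test_that("aggregation never invents values", {
  withr::local_seed(5)
  recs <- make_records(
    make_record(value = runif(1)), make_record(value = runif(1)),
    make_record(value = runif(1), ph = 8),
    make_record(param_kind = "km", unit = "mM", value = runif(1)),
    make_record(param_kind = "km", unit = "mM", value = runif(1)))
  recs$canonical_smiles <- "CCO"
  res <- dedup_and_aggregate(recs)
  expect_true(all(res$entries$value %in% recs$value))
})

test_that("task merge is an outer join on the assay key", {
  mk <- function(keys, kind) {
    df <- do.call(rbind, lapply(keys, function(k) {
      make_record(substrate_smiles = k, param_kind = kind,
                  unit = if (kind == "km") "mM" else "s^-1")
    }))
    df$canonical_smiles <- df$substrate_smiles
    df$log10_value <- 0.5
    df
  }
  j1 <- merge_tasks(mk(c("CA", "CB"), "kcat"), mk(c("CB", "CC"), "km"))
  expect_equal(nrow(j1), 3)
  expect_equal(sum(!is.na(j1$log10_kcat) & !is.na(j1$log10_km)), 1)

  j2 <- merge_tasks(mk(c("CA", "CB"), "kcat"),
                    mk(c("CC", "CD", "CE"), "km"))
  expect_equal(nrow(j2), 5)
  expect_equal(sum(!is.na(j2$log10_kcat) & !is.na(j2$log10_km)), 0)

  keys <- c("CA", "CB", "CC", "CD")
  j3 <- merge_tasks(mk(keys, "kcat"), mk(keys, "km"))
  expect_equal(nrow(j3), 4)
  expect_true(all(!is.na(j3$log10_kcat) & !is.na(j3$log10_km)))
})

test_that("pipeline counts every planted violation exactly", {
  plants <- list(incomplete = 5, tiny = 3, huge = 2, fragment = 4,
                 nonpositive = 5, unknown_unit = 3, bad_mutation = 2)
  gen <- gen_dataset(synth_spec(n_entries = 50, seed = 42,
                                duplicate_rate = 0,
                                planted_violations = plants))
  res <- curate_pipeline(gen$records)
  rep <- res$report
  expect_equal(rep$n_dropped_incomplete, 5)
  expect_equal(rep$n_dropped_unknown_unit, 3)
  expect_equal(rep$n_dropped_mutation, 2)
  expect_equal(rep$n_dropped_heavy_atoms, 3 + 2)  # tiny + huge
  expect_equal(rep$n_dropped_fragment_or_nonpositive, 4 + 5)
  expect_equal(rep$n_input, nrow(gen$records))
  # bookkeeping identity: input = dropped + merged away + surviving
  total_dropped <- rep$n_dropped_incomplete + rep$n_dropped_unknown_unit +
    rep$n_dropped_mutation + rep$n_dropped_heavy_atoms +
    rep$n_dropped_fragment_or_nonpositive
  expect_equal(rep$n_input - total_dropped - rep$n_dropped_duplicate -
                 rep$n_aggregated, rep$n_output)
})

test_that("pipeline handles empty input", {
  res <- curate_pipeline(kinetic_records(make_record()[0, ]))
  expect_equal(nrow(res$entries), 0)
  expect_equal(res$report$n_input, 0)
  expect_equal(res$report$n_output, 0)
})

test_that("unit-variant duplicates of one measurement collapse to one entry", {
  recs <- make_records(
    make_record(value = 2, unit = "s^-1"),
    make_record(value = 120, unit = "min^-1"))  # same measurement
  res <- curate_pipeline(recs)
  expect_equal(nrow(res$entries), 1)
  expect_equal(res$report$n_dropped_duplicate, 1)
  expect_equal(res$entries$log10_kcat, log10(2))
})

test_that("pipeline is idempotent on its own output", {
  gen <- gen_dataset(synth_spec(n_entries = 60, seed = 11))
  first <- curate_pipeline(gen$records)
  second <- curate_pipeline(entries_to_records(first$entries))
  reorder <- function(e) {
    e[order(e$canonical_smiles, e$sequence, e$ph, e$temperature,
            e$organism), ]
  }
  a <- reorder(first$entries); b <- reorder(second$entries)
  rownames(a) <- rownames(b) <- NULL
  expect_equal(b$canonical_smiles, a$canonical_smiles)
  expect_equal(b$log10_kcat, a$log10_kcat, tolerance = 1e-12)
  expect_equal(b$log10_km, a$log10_km, tolerance = 1e-12)
  expect_equal(second$report$n_dropped_duplicate +
                 second$report$n_aggregated, 0)
})

test_that("independent filters commute", {
  withr::local_seed(3)
  recs <- make_records(
    make_record(substrate_smiles = "O", value = 1),
    make_record(substrate_smiles = "CCO", value = -2),
    make_record(substrate_smiles = "CCN.O", value = 0),
    make_record(substrate_smiles = "CCNCC", value = 4),
    make_record(substrate_smiles = "CCC", value = 2))
  ab <- filter_values(filter_structure(recs)$kept)$kept
  ba <- filter_structure(filter_values(recs)$kept)$kept
  expect_equal(as.data.frame(ab), as.data.frame(ba))
})
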