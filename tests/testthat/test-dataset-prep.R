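# Corpus preparation: records, filters, split.

test_that("records carry stereo-free SMILES and round-tripping SELFIES", {
  records <- make_records(c("C[C@@H](N)C(=O)O", "c1ccccc1O", "CCOCC"))
  expect_false(any(grepl("[@/\\\\]", records$smiles_generic)))
  expect_identical(selfies_to_smiles(records$selfies), records$smiles_generic)
  expect_identical(records$token_length, selfies_token_length(records$selfies))
})

test_that("unprocessable molecules are dropped, not fatal", {
  expect_message(records <- make_records(c("CCO", "junk(((", "[Na+].[Cl-]")),
                 "dropped")
  expect_identical(nrow(records), 1L)
  expect_identical(attr(records, "n_dropped"), 2L)
})

test_that("length window bounds are inclusive", {
  # alkanes of n carbons have exactly n tokens
  records <- make_records(vapply(c(29, 30, 40, 50, 51), function(n) {
    strrep("C", n)
  }, character(1)))
  filt <- apply_filters(records, corpus_spec(length_min = 30, length_max = 50))
  expect_identical(filt$records$token_length, c(30L, 40L, 50L))
  expect_identical(unname(filt$counts["input"]), 5L)
  expect_identical(unname(filt$counts["after_length"]), 3L)
})

test_that("element whitelist removes rare heteroatoms and dedup collapses", {
  records <- make_records(c("CCCCP", "CCCCC", "CCCCC", "OCCCCO", "CCCCN"))
  filt <- apply_filters(records, corpus_spec(length_min = 1, length_max = 50))
  # phosphorus-containing molecule removed; duplicate pentane counted once
  expect_false(any(grepl("P", filt$records$smiles_generic)))
  expect_identical(sum(filt$records$smiles_generic == "CCCCC"), 1L)
  counts <- filt$counts
  expect_true(all(diff(counts[c("input", "after_length", "after_elements",
                                "after_dedup")]) <= 0))
})

test_that("filtering everything raises the empty-corpus error", {
  records <- make_records("CCO")
  expect_error(apply_filters(records, corpus_spec(length_min = 30,
                                                  length_max = 50)),
               "empty corpus")
})

test_that("train/validation split has exact sizes and is reproducible", {
  records <- data.frame(id = seq_len(121000L))
  spec <- corpus_spec(rng_seed = 1L)
  split <- train_val_split(records, spec)
  expect_identical(nrow(split$train), 108900L)
  expect_identical(nrow(split$validation), 12100L)
  expect_identical(sort(c(split$train$id, split$validation$id)), records$id)
  split2 <- train_val_split(records, spec)
  expect_identical(split$validation$id, split2$validation$id)
  # 10 records -> 9/1
  tiny <- train_val_split(data.frame(id = 1:10), spec)
  expect_identical(nrow(tiny$train), 9L)
  expect_identical(nrow(tiny$validation), 1L)
})

test_that("smi files read back with optional ids", {
  path <- withr::local_tempfile(fileext = ".smi")
  writeLines(c("CCO\tmol1", "c1ccccc1"), path)
  smi <- read_smi(path)
  expect_identical(smi$smiles, c("CCO", "c1ccccc1"))
  expect_identical(smi$id, c("mol1", NA_character_))
})

test_that("csv input honours a configurable smiles column", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(id = 1:2, structure = c("CCO", "CCN")), path,
            row.names = FALSE)
  got <- read_smiles_csv(path, smiles_col = "structure")
  expect_identical(got$smiles, c("CCO", "CCN"))
  expect_error(read_smiles_csv(path), "'smiles' not found")
})
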