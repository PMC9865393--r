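# The SELFIES codec: tokenisation, robust decoding, round trips.

test_that("tokeniser splits bracketed units and rejects malformed input", {
  expect_identical(selfies_tokens("[C][=C][Branch1][C][O]"),
                   c("[C]", "[=C]", "[Branch1]", "[C]", "[O]"))
  expect_identical(selfies_tokens(""), character(0))
  expect_identical(selfies_token_length(c("[C][C][C]", "")), c(3L, 0L))
  expect_error(selfies_tokens("[C]C[O]"), "malformed")
})

test_that("linear alkanes encode to one token per carbon", {
  for (n in 3:6) {
    sf <- smiles_to_selfies(strrep("C", n))
    # independent token-splitting oracle
    expect_identical(length(strsplit(sf, "(?<=\\])(?=\\[)", perl = TRUE)[[1]]),
                     n)
    expect_identical(sf, strrep("[C]", n))
  }
})

test_that("SMILES -> SELFIES -> SMILES is the identity on canonical generic form", {
  drugs <- c("CC(=O)Oc1ccccc1C(=O)O",        # aspirin
             "Cn1cnc2c1c(=O)n(C)c(=O)n2C",   # caffeine
             "CC(C)Cc1ccc(cc1)C(C)C(=O)O",   # ibuprofen
             "C[C@@H](N)C(=O)O",             # L-alanine (stereo stripped)
             "CS(=O)(=O)c1ccccc1",           # hypervalent sulfur
             "C#N", "C1CC1", "c1ccc2ccccc2c1",
             "O=C(Nc1ccc(Cl)cc1)c1ccncc1", "CCOC(=O)C1CCN(C)CC1")
  canon <- canonicalize_generic(drugs)
  back <- selfies_to_smiles(smiles_to_selfies(canon))
  expect_identical(back, canon)
})

test_that("every random token string decodes to a valid molecule", {
  spec <- fixture_spec(n_molecules = 150L, length_range = c(5L, 45L),
                       rng_seed = 202L)
  raw <- selfies_to_smiles(random_selfies(spec), canonical = FALSE)
  expect_true(all(nzchar(raw)))
  canon <- canonicalize_generic(raw)  # errors if anything is invalid
  expect_true(all(nzchar(canon)))
})

test_that("decoded random molecules re-encode consistently", {
  spec <- fixture_spec(n_molecules = 40L, length_range = c(10L, 30L),
                       rng_seed = 203L)
  canon <- selfies_to_smiles(random_selfies(spec))
  again <- selfies_to_smiles(smiles_to_selfies(canon))
  expect_identical(again, canon)
})

test_that("unsupported species are rejected with a clear error", {
  expect_error(smiles_to_selfies("C[N+](C)(C)C"), "charged")
  expect_error(smiles_to_selfies("CCB(O)O"), "unsupported element")
  expect_identical(smiles_to_selfies("C[N+](C)(C)C", strict = FALSE),
                   NA_character_)
})
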