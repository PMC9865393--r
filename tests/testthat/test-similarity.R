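# Fingerprints and Tanimoto similarity.

make_fp <- function(bits, n_bits = 16L) {
  structure(list(bits = as.integer(bits), n_bits = as.integer(n_bits)),
            class = "fingerprint")
}

# Brute-force oracle over dense logical vectors.
tanimoto_oracle <- function(a, b) {
  va <- vb <- logical(a$n_bits)
  va[a$bits + 1L] <- TRUE
  vb[b$bits + 1L] <- TRUE
  if (!any(va | vb)) return(1)
  sum(va & vb) / sum(va | vb)
}

test_that("tanimoto contracts: identity, disjointness, hand-counted overlap", {
  expect_identical(tanimoto(make_fp(c(1, 5, 9)), make_fp(c(1, 5, 9))), 1)
  expect_identical(tanimoto(make_fp(c(1, 2)), make_fp(c(3, 4))), 0)
  expect_identical(tanimoto(make_fp(c(1, 2, 3)), make_fp(c(2, 3, 4))), 0.5)
  expect_identical(tanimoto(make_fp(integer(0)), make_fp(integer(0))), 1)
  expect_error(tanimoto(make_fp(1, 16), make_fp(1, 32)), "lengths differ")
})

test_that("tanimoto agrees with the brute-force set-count oracle", {
  set.seed(8)
  for (i in 1:50) {
    a <- make_fp(sample(0:63, sample(0:20, 1)), 64L)
    b <- make_fp(sample(0:63, sample(0:20, 1)), 64L)
    expect_identical(tanimoto(a, b), tanimoto_oracle(a, b))
    expect_identical(tanimoto(a, b), tanimoto(b, a))  # symmetry
  }
})

test_that("molecular fingerprints are deterministic and separate isomers", {
  fps <- fingerprint(c("CCO", "CCO", "COC", "CC"))
  expect_identical(fps[[1]]$bits, fps[[2]]$bits)
  expect_false(identical(fps[[1]]$bits, fps[[3]]$bits))  # structural isomers
  # any bonded molecule sets at least one bit (a path fingerprint of
  # methane is empty: there are no paths)
  expect_gt(length(fps[[4]]$bits), 0)
  expect_true(all(fps[[1]]$bits >= 0 & fps[[1]]$bits < fps[[1]]$n_bits))
})

test_that("similarity reports round-trip through their file outputs", {
  rep3 <- similarity_report(c("CCO", "CCN"), c("CCO", "c1ccccc1"))
  prefix <- file.path(withr::local_tempdir(), "sim")
  paths <- write_similarity_report(rep3, prefix)
  back <- as.matrix(read.csv(paste0(prefix, "_matrix.csv"), row.names = 1,
                             check.names = FALSE))
  expect_equal(unname(back), unname(rep3$matrix))
  summ <- jsonlite::read_json(paste0(prefix, "_summary.json"))
  expect_equal(summ$mean, unname(rep3$summary[["mean"]]))
})

test_that("similarity report: matrix shape, self-similarity, summaries", {
  rep1 <- similarity_report("CCO", "CCO")
  expect_identical(unname(rep1$matrix), matrix(1, 1, 1))
  smis <- c("CCO", "CCN", "c1ccccc1")
  rep3 <- similarity_report(smis, smis)
  expect_identical(dim(rep3$matrix), c(3L, 3L))
  expect_equal(unname(diag(rep3$matrix)), rep(1, 3))
  s <- rep3$summary
  expect_true(s[["min"]] >= 0 && s[["min"]] <= s[["mean"]] &&
                s[["mean"]] <= s[["max"]] && s[["max"]] <= 1)
  expect_equal(unname(s[["mean"]]), mean(rep3$matrix))
  expect_identical(sum(rep3$histogram$count), length(rep3$matrix))
})
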