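# Sequence alphabet and one-hot coder.

test_that("alphabet assigns unique characters and reserves the markers", {
  ab <- build_alphabet(c("[C][C]", "[C][N][O]"))
  expect_s3_class(ab, "sequence_alphabet")
  expect_identical(length(ab$token_to_char), 3L)  # [C], [N], [O]
  expect_false(any(ab$token_to_char %in% c("!", "E")))
  expect_identical(anyDuplicated(ab$token_to_char), 0L)
  # char <-> index maps invert each other
  expect_identical(unname(ab$char_to_index[ab$chars]), seq_along(ab$chars))
})

test_that("single-molecule corpus yields 1 molecule token plus 2 markers", {
  ab <- build_alphabet("[C][C]")
  expect_identical(length(ab$chars), 3L)
})

test_that("alphabet capacity errors on impossibly rich corpora", {
  many <- paste0("[T", seq_len(120), "]", collapse = "")
  expect_error(build_alphabet(many), "capacity")
})

test_that("encode/decode sequences are mutually inverse", {
  ts <- tiny_setup()
  seqs <- encode_sequence(ts$corpus$selfies, ts$alphabet)
  expect_identical(decode_sequence(seqs, ts$alphabet), ts$corpus$selfies)
  expect_identical(encode_sequence("", ts$alphabet), "")
  expect_error(encode_sequence("[Xx][C]", ts$alphabet), "\\[Xx\\]")
})

test_that("alphabet serialisation round-trips bit-exactly", {
  ts <- tiny_setup()
  path <- withr::local_tempfile(fileext = ".json")
  save_alphabet(ts$alphabet, path)
  reloaded <- load_alphabet(path)
  expect_identical(reloaded, ts$alphabet)
})

test_that("vectorize pads with the end marker after the start marker", {
  ab <- build_alphabet("[A][B]")
  a <- ab$token_to_char[["[A]"]]
  b <- ab$token_to_char[["[B]"]]
  oh <- vectorize(paste0(a, b), ab)  # "ab" with embed 4
  expect_identical(nrow(oh), ab$embed)
  expect_true(all(rowSums(oh) == 1))
  decoded_chars <- ab$chars[max.col(oh)]
  expect_identical(decoded_chars, c("!", a, b, rep("E", ab$embed - 3L)))
})

test_that("devectorize inverts vectorize for every fixture sequence", {
  ts <- tiny_setup()
  for (s in ts$sequences[1:20]) {
    expect_identical(devectorize(vectorize(s, ts$alphabet), ts$alphabet), s)
  }
})

test_that("sequences longer than embed - 2 are refused", {
  ab <- build_alphabet("[C][C][C]", embed = 5)
  expect_error(vectorize(strrep(ab$token_to_char[["[C]"]], 4), ab),
               "longer than embed - 2")
})

test_that("full chain SELFIES -> sequence -> one-hot -> SELFIES is the identity", {
  ts <- tiny_setup()
  for (i in seq_len(10)) {
    sf <- ts$corpus$selfies[i]
    seqc <- encode_sequence(sf, ts$alphabet)
    back <- decode_sequence(devectorize(vectorize(seqc, ts$alphabet),
                                        ts$alphabet), ts$alphabet)
    expect_identical(back, sf)
  }
})
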