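# The LSTM encoder-decoder: gradients, training, encoding, decoding.

test_that("analytic BPTT gradients match finite differences", {
  set.seed(3)
  V <- 6L; H <- 5L; B <- 3L; T <- 7L
  params <- selfgen:::lstm_init_params(V, H)
  idx <- matrix(sample(seq_len(V), B * T, replace = TRUE), B, T)
  res <- selfgen:::seq2seq_loss(params, idx, H)
  eps <- 1e-6
  for (nm in names(params)) {
    for (k in 1:4) {
      pos <- sample(length(params[[nm]]), 1)
      up <- params; up[[nm]][pos] <- up[[nm]][pos] + eps
      dn <- params; dn[[nm]][pos] <- dn[[nm]][pos] - eps
      numeric_grad <- (selfgen:::seq2seq_loss(up, idx, H, FALSE)$loss -
                         selfgen:::seq2seq_loss(dn, idx, H, FALSE)$loss) / (2 * eps)
      expect_equal(res$grads[[nm]][pos], numeric_grad, tolerance = 1e-4)
    }
  }
})

test_that("training reduces the loss and records a full history", {
  model <- tiny_model()
  hist <- model$history
  expect_identical(nrow(hist), model$config$max_epochs)
  expect_true(all(is.finite(hist$loss)) && all(hist$loss >= 0))
  expect_lt(hist$loss[nrow(hist)], hist$loss[1])
})

test_that("validation loss decreases over the first epochs", {
  ts <- tiny_setup()
  cfg <- model_config(lstm_units = 32L, max_epochs = 10L, batch_size = 8L,
                      rng_seed = 5L)
  model <- train_seq2seq(ts$sequences[1:30], ts$sequences[31:40],
                         ts$alphabet, cfg)
  expect_true(all(is.finite(model$history$val_loss)))
  expect_lt(model$history$val_loss[10], model$history$val_loss[1])
})

test_that("training on an empty set errors", {
  ts <- tiny_setup()
  expect_error(train_seq2seq(character(0), character(0), ts$alphabet,
                             model_config(max_epochs = 1L)),
               "empty")
})

test_that("encoding is deterministic, correctly sized and separates molecules", {
  ts <- tiny_setup()
  model <- tiny_model()
  st1 <- encode_latent(model, ts$sequences[1:2], ts$alphabet)
  st2 <- encode_latent(model, ts$sequences[1:2], ts$alphabet)
  expect_identical(st1, st2)
  expect_identical(length(st1[[1]]$h), model$config$lstm_units)
  expect_identical(length(st1[[1]]$c), model$config$lstm_units)
  expect_false(identical(st1[[1]]$h, st1[[2]]$h))
})

test_that("decoder emissions are probability distributions and decoding stops", {
  ts <- tiny_setup()
  model <- tiny_model()
  st <- encode_latent(model, ts$sequences[1], ts$alphabet)[[1]]
  out <- decode_states(model, st, ts$alphabet, return_probs = TRUE)
  expect_true(all(out$probs >= 0))
  expect_equal(unname(rowSums(out$probs)), rep(1, nrow(out$probs)))
  expect_lte(nchar(out$sequence), ts$alphabet$embed - 2L)
  # decoded sequences map to syntactically decodable SELFIES
  sf <- decode_sequence(out$sequence, ts$alphabet)
  expect_true(nzchar(selfies_to_smiles(sf, canonical = FALSE)) || !nzchar(sf))
})

test_that("non-finite latent states are rejected", {
  ts <- tiny_setup()
  model <- tiny_model()
  st <- encode_latent(model, ts$sequences[1], ts$alphabet)[[1]]
  st$h[1] <- NaN
  expect_error(decode_states(model, st, ts$alphabet), "non-finite")
})

test_that("a single-molecule corpus is reconstructed exactly after training", {
  ts <- tiny_setup()
  seq1 <- ts$sequences[1]
  cfg <- model_config(lstm_units = 32L, max_epochs = 60L, batch_size = 1L,
                      rng_seed = 9L)
  model <- train_seq2seq(seq1, character(0), ts$alphabet, cfg)
  st <- encode_latent(model, seq1, ts$alphabet)[[1]]
  expect_identical(decode_states(model, st, ts$alphabet), seq1)
})
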