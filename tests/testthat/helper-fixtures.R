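# Shared fixtures, built once per test run and cached.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, builder) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, builder(), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# Small, fast corpus (short molecules) for coder/model mechanics.
tiny_setup <- function() {
  cached("tiny", function() {
    corpus <- random_corpus(fixture_spec(n_molecules = 40L,
                                         length_range = c(8L, 16L),
                                         rng_seed = 101L))
    alphabet <- build_alphabet(corpus$selfies)
    sequences <- encode_sequence(corpus$selfies, alphabet)
    list(corpus = corpus, alphabet = alphabet, sequences = sequences)
  })
}

# Tiny trained model over the tiny corpus: enough epochs for the loss
# to fall well below its starting value, cheap enough for unit tests.
tiny_model <- function() {
  cached("tiny_model", function() {
    ts <- tiny_setup()
    cfg <- model_config(lstm_units = 48L, max_epochs = 40L, batch_size = 8L,
                        learning_rate = 0.01, rng_seed = 7L)
    train_seq2seq(ts$sequences, character(0), ts$alphabet, cfg)
  })
}

# Study-condition corpus (100 molecules, 30-50 tokens) and the model
# overfit on it for the reconstruction experiment; shared between the
# acceptance checks that need a faithful autoencoder.
overfit_setup <- function() {
  cached("overfit", function() {
    corpus <- random_corpus(fixture_spec(n_molecules = 100L,
                                         length_range = c(30L, 50L),
                                         rng_seed = 11L))
    alphabet <- build_alphabet(corpus$selfies)
    sequences <- encode_sequence(corpus$selfies, alphabet)
    model <- train_seq2seq(sequences, character(0), alphabet,
                           model_config(rng_seed = 7L))
    list(corpus = corpus, alphabet = alphabet, sequences = sequences,
         model = model)
  })
}

# A trained fragment table over the bundled easy/hard sets.
fixture_fragment_table <- function() {
  cached("fragment_table", function() {
    sets <- make_easy_hard_sets(rng_seed = 42L)
    list(table = train_fragment_table(sets$easy, sets$hard),
         sets = sets)
  })
}
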