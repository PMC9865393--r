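# User-facing sequence-to-sequence model: training, encoding molecules
# into latent states, and greedy character-by-character decoding.

#' Model configuration
#'
#' @param lstm_units Hidden/cell state width of the (single-layer)
#'   encoder and decoder LSTMs.
#' @param max_epochs Training epoch budget (default 200).
#' @param batch_size Minibatch size.
#' @param learning_rate Initial Adam learning rate.
#' @param lr_decay Per-epoch multiplicative learning-rate decay
#'   (default 0.99; 1 disables the schedule).  Decay stabilises the
#'   late, near-interpolation phase of training.
#' @param reverse_encoder Feed the encoder the sequence right to left
#'   (default `TRUE`): the classic input-reversal trick that shortens
#'   the path between a sequence's head and the decoder's first
#'   emissions.
#' @param rng_seed Seed controlling initialisation and batch shuffling.
#' @return Object of class `model_config`.
#' @export
model_config <- function(lstm_units = 128L, max_epochs = 200L,
                         batch_size = 10L, learning_rate = 0.01,
                         lr_decay = 0.99, reverse_encoder = TRUE,
                         rng_seed = 7L) {
  stopifnot(lstm_units >= 1, max_epochs >= 1, batch_size >= 1,
            learning_rate > 0, lr_decay > 0, lr_decay <= 1)
  structure(list(lstm_units = as.integer(lstm_units),
                 max_epochs = as.integer(max_epochs),
                 batch_size = as.integer(batch_size),
                 learning_rate = learning_rate,
                 lr_decay = lr_decay,
                 reverse_encoder = isTRUE(reverse_encoder),
                 rng_seed = as.integer(rng_seed)),
            class = "model_config")
}

#' Train the recurrent encoder-decoder
#'
#' Autoencoder training with teacher forcing: the encoder reads the
#' padded one-hot sequence into its final hidden/cell state, the decoder
#' is fed the same sequence shifted right by the start marker and scored
#' with categorical cross-entropy against the next character at every
#' position (end-marker padding included).
#'
#' @param train_sequences,val_sequences Character vectors of molecular
#'   sequences (from [encode_sequence()]).  `val_sequences` may be
#'   empty, in which case no validation loss is recorded.
#' @param alphabet The shared [build_alphabet()] result.
#' @param config A [model_config()].
#' @param verbose Emit a progress message every 10 epochs.
#' @return Object of class `seq2seq_model` with elements `params`,
#'   `config`, `chars` (the alphabet characters the model was trained
#'   on) and `history` (data frame: epoch, loss, val_loss).
#' @export
train_seq2seq <- function(train_sequences, val_sequences = character(0),
                          alphabet, config = model_config(),
                          verbose = FALSE) {
  stopifnot(inherits(alphabet, "sequence_alphabet"),
            inherits(config, "model_config"))
  if (length(train_sequences) == 0) {
    stop("training set is empty", call. = FALSE)
  }
  idx_train <- sequences_to_indices(train_sequences, alphabet)
  idx_val <- if (length(val_sequences) > 0) {
    sequences_to_indices(val_sequences, alphabet)
  }
  V <- length(alphabet$chars)
  H <- config$lstm_units
  n <- nrow(idx_train)

  with_seed(config$rng_seed, {
    params <- lstm_init_params(V, H)
    opt <- adam_init(params)
    history <- data.frame(epoch = integer(0), loss = numeric(0),
                          val_loss = numeric(0))
    for (epoch in seq_len(config$max_epochs)) {
      lr <- config$learning_rate * config$lr_decay^(epoch - 1L)
      ord <- sample.int(n)
      starts <- seq(1, n, by = config$batch_size)
      epoch_loss <- 0
      for (s in starts) {
        rows <- ord[s:min(s + config$batch_size - 1L, n)]
        res <- seq2seq_loss(params, idx_train[rows, , drop = FALSE], H,
                            reverse_encoder = config$reverse_encoder)
        upd <- adam_step(params, res$grads, opt, lr = lr)
        params <- upd$params
        opt <- upd$state
        epoch_loss <- epoch_loss + res$loss * length(rows)
      }
      epoch_loss <- epoch_loss / n
      val_loss <- if (!is.null(idx_val)) {
        seq2seq_loss(params, idx_val, H, want_grads = FALSE,
                     reverse_encoder = config$reverse_encoder)$loss
      } else {
        NA_real_
      }
      history <- rbind(history, data.frame(epoch = epoch, loss = epoch_loss,
                                           val_loss = val_loss))
      if (verbose && (epoch %% 10 == 0 || epoch == 1)) {
        message(sprintf("epoch %3d  loss %.4f  val %.4f",
                        epoch, epoch_loss, val_loss))
      }
    }
    structure(list(params = params, config = config,
                   chars = alphabet$chars, embed = alphabet$embed,
                   history = history),
              class = "seq2seq_model")
  })
}

#' @export
print.seq2seq_model <- function(x, ...) {
  cat("<seq2seq_model>", x$config$lstm_units, "LSTM units,",
      length(x$chars), "characters, embed", x$embed, "-",
      nrow(x$history), "epochs trained (final loss",
      sprintf("%.4f)", utils::tail(x$history$loss, 1)), "\n")
  invisible(x)
}

.check_model_alphabet <- function(model, alphabet) {
  if (!identical(model$chars, alphabet$chars)) {
    stop("model and alphabet character sets differ", call. = FALSE)
  }
}

#' Encode molecular sequences into latent states
#'
#' Runs the trained encoder over each padded sequence and returns its
#' final hidden/cell state pair -- the latent anchor around which new
#' molecules are sampled.
#'
#' @param model A [train_seq2seq()] result.
#' @param sequences Character vector of molecular sequences.
#' @param alphabet The alphabet the model was trained with.
#' @return A list of `latent_state` objects (`h` and `c`, each of length
#'   `lstm_units`).
#' @export
encode_latent <- function(model, sequences, alphabet) {
  stopifnot(inherits(model, "seq2seq_model"))
  .check_model_alphabet(model, alphabet)
  idx <- sequences_to_indices(sequences, alphabet)
  H <- model$config$lstm_units
  B <- nrow(idx)
  h <- matrix(0, B, H); c <- matrix(0, B, H)
  cols <- if (isTRUE(model$config$reverse_encoder)) {
    rev(seq_len(ncol(idx)))
  } else {
    seq_len(ncol(idx))
  }
  for (t in cols) {
    st <- .lstm_step(model$params$Wx_e, model$params$Wh_e, model$params$b_e,
                     idx[, t], h, c)
    h <- st$h; c <- st$c
  }
  lapply(seq_len(B), function(i) {
    structure(list(h = h[i, ], c = c[i, ]), class = "latent_state")
  })
}

#' Decode a latent state into a molecular sequence
#'
#' Greedy character-by-character generation: starting from the start
#' marker, the decoder emits the argmax character at each step and
#' advances its recurrent state, stopping at the end marker `'E'` or
#' after `embed - 2` characters.
#'
#' @param model A [train_seq2seq()] result.
#' @param state A `latent_state` (from [encode_latent()] or
#'   [perturb_latent()]).
#' @param alphabet The alphabet the model was trained with.
#' @param return_probs If `TRUE`, also return the per-step emission
#'   probability matrix.
#' @return The decoded molecular sequence (markers excluded); with
#'   `return_probs = TRUE`, `list(sequence=, probs=)`.
#' @export
decode_states <- function(model, state, alphabet, return_probs = FALSE) {
  stopifnot(inherits(model, "seq2seq_model"), inherits(state, "latent_state"))
  .check_model_alphabet(model, alphabet)
  H <- model$config$lstm_units
  if (length(state$h) != H || length(state$c) != H) {
    stop("latent state width does not match lstm_units", call. = FALSE)
  }
  if (!all(is.finite(state$h)) || !all(is.finite(state$c))) {
    stop("latent state contains non-finite entries", call. = FALSE)
  }
  h <- matrix(state$h, 1, H)
  c <- matrix(state$c, 1, H)
  V <- length(alphabet$chars)
  x <- alphabet$char_to_index[[alphabet$start_char]]
  end_idx <- alphabet$char_to_index[[alphabet$end_char]]
  max_len <- alphabet$embed - 2L
  out <- character(0)
  probs <- if (return_probs) matrix(numeric(0), 0, V)
  repeat {
    st <- .lstm_step(model$params$Wx_d, model$params$Wh_d, model$params$b_d,
                     x, h, c)
    h <- st$h; c <- st$c
    logits <- h %*% model$params$Wy + model$params$by
    p <- exp(logits - max(logits))
    p <- p / sum(p)
    if (return_probs) probs <- rbind(probs, p)
    x <- which.max(p)
    if (x == end_idx || length(out) >= max_len) break
    out <- c(out, alphabet$chars[x])
  }
  sequence <- paste(out, collapse = "")
  if (return_probs) list(sequence = sequence, probs = probs) else sequence
}
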