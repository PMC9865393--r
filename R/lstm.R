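# Single-layer LSTM encoder-decoder over one-hot molecular sequences.
# Compact batch-vectorised implementation: one-hot inputs are handled by
# row indexing (never materialised), all state math is dense matrix
# algebra over the batch.  Gate layout in the 4H-wide weight blocks:
# [input | forget | candidate | output].

.sigmoid <- function(x) 1 / (1 + exp(-x))

.glorot <- function(nr, nc) {
  lim <- sqrt(6 / (nr + nc))
  matrix(stats::runif(nr * nc, -lim, lim), nr, nc)
}

# Parameter set; forget-gate bias starts at 1 (standard remedy against
# early vanishing of the cell path).
lstm_init_params <- function(V, H) {
  b_enc <- rep(0, 4 * H); b_enc[(H + 1):(2 * H)] <- 1
  b_dec <- rep(0, 4 * H); b_dec[(H + 1):(2 * H)] <- 1
  list(Wx_e = .glorot(V, 4 * H), Wh_e = .glorot(H, 4 * H), b_e = b_enc,
       Wx_d = .glorot(V, 4 * H), Wh_d = .glorot(H, 4 * H), b_d = b_dec,
       Wy = .glorot(H, V), by = rep(0, V))
}

# One LSTM step for a batch. x_idx: integer vector (B) of one-hot
# positions; h, c: B x H.  Returns the new state plus everything the
# backward pass needs.
.lstm_step <- function(Wx, Wh, b, x_idx, h, c) {
  H <- ncol(h)
  B <- nrow(h)
  z <- Wx[x_idx, , drop = FALSE] + h %*% Wh + rep(b, each = B)
  i <- .sigmoid(z[, 1:H, drop = FALSE])
  f <- .sigmoid(z[, (H + 1):(2 * H), drop = FALSE])
  g <- tanh(z[, (2 * H + 1):(3 * H), drop = FALSE])
  o <- .sigmoid(z[, (3 * H + 1):(4 * H), drop = FALSE])
  c_new <- f * c + i * g
  tc <- tanh(c_new)
  h_new <- o * tc
  list(h = h_new, c = c_new, i = i, f = f, g = g, o = o,
       tc = tc, h_prev = h, c_prev = c, x_idx = x_idx)
}

# Backward through one step.  dh, dc: gradients arriving at (h_new,
# c_new).  Returns gradients for the step inputs and parameter
# increments.
.lstm_step_back <- function(Wx, Wh, cache, dh, dc) {
  i <- cache$i; f <- cache$f; g <- cache$g; o <- cache$o; tc <- cache$tc
  do <- dh * tc * o * (1 - o)
  dcf <- dc + dh * o * (1 - tc^2)
  di <- dcf * g * i * (1 - i)
  df <- dcf * cache$c_prev * f * (1 - f)
  dg <- dcf * i * (1 - g^2)
  dz <- cbind(di, df, dg, do)
  list(dz = dz,
       dWh = crossprod(cache$h_prev, dz),
       db = colSums(dz),
       dh_prev = dz %*% t(Wh),
       dc_prev = dcf * f)
}

# Scatter-add dz rows into the one-hot weight gradient.
.acc_dWx <- function(dWx, dz, x_idx) {
  rs <- rowsum(dz, group = x_idx)
  rows <- as.integer(rownames(rs))
  dWx[rows, ] <- dWx[rows, , drop = FALSE] + rs
  dWx
}

# Full forward + loss (+ gradients) for a batch of index sequences.
# idx: B x T padded index matrix ('!' in column 1, 'E' padding at the
# end).  The encoder reads all T columns (optionally right to left, the
# classic input-reversal trick that shortens the path from a sequence's
# head to the decoder's first emissions); the decoder is teacher-forced
# with columns 1..T-1 and scored against columns 2..T.
# Mean categorical cross-entropy over batch x (T-1) positions.
# `backend = "cpp"` dispatches to the compiled implementation
# (identical math; cross-checked in the tests).
seq2seq_loss <- function(params, idx, H, want_grads = TRUE,
                         reverse_encoder = FALSE, backend = "cpp") {
  if (identical(backend, "cpp")) {
    res <- .cpp_seq2seq_loss(params, idx, H, want_grads, reverse_encoder)
    if (want_grads) {
      for (nm in c("b_e", "b_d", "by")) {
        res$grads[[nm]] <- as.numeric(res$grads[[nm]])
      }
    }
    return(res)
  }
  B <- nrow(idx); T <- ncol(idx)
  V <- nrow(params$Wx_e)
  h <- matrix(0, B, H); c <- matrix(0, B, H)
  enc_cols <- if (reverse_encoder) rev(seq_len(T)) else seq_len(T)
  enc_cache <- vector("list", T)
  for (t in seq_len(T)) {
    st <- .lstm_step(params$Wx_e, params$Wh_e, params$b_e,
                     idx[, enc_cols[t]], h, c)
    enc_cache[[t]] <- st
    h <- st$h; c <- st$c
  }

  Td <- T - 1L
  dec_cache <- vector("list", Td)
  probs <- vector("list", Td)
  loss <- 0
  denom <- B * Td
  for (t in seq_len(Td)) {
    st <- .lstm_step(params$Wx_d, params$Wh_d, params$b_d, idx[, t], h, c)
    dec_cache[[t]] <- st
    h <- st$h; c <- st$c
    logits <- h %*% params$Wy + rep(params$by, each = B)
    logits <- logits - apply(logits, 1, max)
    ex <- exp(logits)
    p <- ex / rowSums(ex)
    probs[[t]] <- p
    tgt <- idx[, t + 1L]
    loss <- loss - sum(log(pmax(p[cbind(seq_len(B), tgt)], 1e-12))) / denom
  }
  if (!want_grads) return(list(loss = loss))

  grads <- list(Wx_e = matrix(0, V, 4 * H), Wh_e = matrix(0, H, 4 * H),
                b_e = rep(0, 4 * H),
                Wx_d = matrix(0, V, 4 * H), Wh_d = matrix(0, H, 4 * H),
                b_d = rep(0, 4 * H),
                Wy = matrix(0, H, V), by = rep(0, V))
  dh <- matrix(0, B, H); dc <- matrix(0, B, H)
  for (t in rev(seq_len(Td))) {
    p <- probs[[t]]
    tgt <- idx[, t + 1L]
    dy <- p
    dy[cbind(seq_len(B), tgt)] <- dy[cbind(seq_len(B), tgt)] - 1
    dy <- dy / denom
    grads$Wy <- grads$Wy + crossprod(dec_cache[[t]]$h, dy)
    grads$by <- grads$by + colSums(dy)
    dh <- dh + dy %*% t(params$Wy)
    bk <- .lstm_step_back(params$Wx_d, params$Wh_d, dec_cache[[t]], dh, dc)
    grads$Wx_d <- .acc_dWx(grads$Wx_d, bk$dz, dec_cache[[t]]$x_idx)
    grads$Wh_d <- grads$Wh_d + bk$dWh
    grads$b_d <- grads$b_d + bk$db
    dh <- bk$dh_prev; dc <- bk$dc_prev
  }
  for (t in rev(seq_len(T))) {
    bk <- .lstm_step_back(params$Wx_e, params$Wh_e, enc_cache[[t]], dh, dc)
    grads$Wx_e <- .acc_dWx(grads$Wx_e, bk$dz, enc_cache[[t]]$x_idx)
    grads$Wh_e <- grads$Wh_e + bk$dWh
    grads$b_e <- grads$b_e + bk$db
    dh <- bk$dh_prev; dc <- bk$dc_prev
  }
  list(loss = loss, grads = grads)
}

# Adam with global-norm gradient clipping.
adam_init <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

adam_step <- function(params, grads, state, lr = 0.01, beta1 = 0.9,
                      beta2 = 0.999, eps = 1e-8, clip = 5) {
  gnorm <- sqrt(sum(vapply(grads, function(g) sum(g^2), numeric(1))))
  if (is.finite(gnorm) && gnorm > clip) {
    grads <- lapply(grads, function(g) g * (clip / gnorm))
  }
  state$t <- state$t + 1L
  bc1 <- 1 - beta1^state$t
  bc2 <- 1 - beta2^state$t
  for (nm in names(params)) {
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * grads[[nm]]
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * grads[[nm]]^2
    mhat <- state$m[[nm]] / bc1
    vhat <- state$v[[nm]] / bc2
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}
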