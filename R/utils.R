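# Small shared helpers.

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# RNG stream.
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(expr)
}

# Deterministic polynomial string hash onto [0, 1): used by the mock
# docking backend so energies are stable across platforms and sessions.
string_hash01 <- function(x) {
  vapply(x, function(s) {
    h <- 0
    for (code in utf8ToInt(s)) h <- (h * 131 + code) %% 2147483647
    h / 2147483647
  }, numeric(1), USE.NAMES = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
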