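# The sequence alphabet: bijections between SELFIES tokens,
# mono-character "molecular sequences", integer indices and one-hot
# rows, with '!' as the start marker and 'E' as the combined end/padding
# marker.

# Character pool for molecule tokens: printable ASCII minus the two
# markers; quote, backslash and comma are also withheld so alphabets and
# sequences serialise cleanly to JSON/CSV.
.alphabet_char_pool <- function() {
  pool <- vapply(33:126, function(i) rawToChar(as.raw(i)), character(1))
  setdiff(pool, c("!", "E", "\"", "\\", ","))
}

#' Build a sequence alphabet from a SELFIES corpus
#'
#' Collects the distinct SELFIES tokens of the corpus and assigns each a
#' single printable character (in sorted-token order, so the alphabet
#' depends only on the token set).  `'!'` (start) and `'E'` (end and
#' padding) are reserved and never assigned to molecule tokens.
#'
#' @param selfies Character vector of SELFIES strings (the corpus).
#' @param embed Total padded sequence length.  Default: longest
#'   molecular sequence in the corpus plus 2 marker positions, capped by
#'   `embed_cap`.
#' @param embed_cap Upper bound on `embed` (default 65, the deployed
#'   model's handling limit).
#' @return Object of class `sequence_alphabet`: `token_to_char`,
#'   `char_to_token`, `chars` (index -> character, markers first),
#'   `char_to_index`, `start_char`, `end_char`, `embed`.
#' @export
build_alphabet <- function(selfies, embed = NULL, embed_cap = 65L) {
  stopifnot(is.character(selfies), length(selfies) >= 1)
  token_list <- lapply(selfies, selfies_tokens)
  tokens <- sort(unique(unlist(token_list, use.names = FALSE)))
  if (length(tokens) == 0) stop("corpus contains no tokens", call. = FALSE)
  pool <- .alphabet_char_pool()
  if (length(tokens) > length(pool)) {
    stop("corpus has ", length(tokens), " distinct tokens; alphabet capacity is ",
         length(pool), call. = FALSE)
  }
  token_to_char <- stats::setNames(pool[seq_along(tokens)], tokens)
  longest <- max(lengths(token_list))
  if (is.null(embed)) embed <- min(longest + 2L, embed_cap)
  embed <- as.integer(embed)
  if (embed < longest + 2L) {
    stop("embed (", embed, ") is smaller than the longest molecular sequence + 2 (",
         longest + 2L, ")", call. = FALSE)
  }
  chars <- c("!", "E", unname(token_to_char))
  structure(list(token_to_char = token_to_char,
                 char_to_token = stats::setNames(names(token_to_char),
                                                 unname(token_to_char)),
                 chars = chars,
                 char_to_index = stats::setNames(seq_along(chars), chars),
                 start_char = "!", end_char = "E",
                 embed = embed),
            class = "sequence_alphabet")
}

#' @export
print.sequence_alphabet <- function(x, ...) {
  cat("<sequence_alphabet>", length(x$token_to_char), "molecule tokens + 2 markers;",
      "embed =", x$embed, "\n")
  invisible(x)
}

#' Encode SELFIES as molecular sequences
#'
#' Replaces every SELFIES token by its alphabet character, producing a
#' one-character-per-token "molecular sequence".
#'
#' @param selfies Character vector of SELFIES strings.
#' @param alphabet A [build_alphabet()] result.
#' @return Character vector of molecular sequences.
#' @export
encode_sequence <- function(selfies, alphabet) {
  stopifnot(inherits(alphabet, "sequence_alphabet"))
  vapply(selfies, function(s) {
    toks <- selfies_tokens(s)
    if (length(toks) == 0) return("")
    chars <- alphabet$token_to_char[toks]
    if (anyNA(chars)) {
      stop("token(s) not in alphabet: ",
           paste(unique(toks[is.na(chars)]), collapse = ", "), call. = FALSE)
    }
    paste(chars, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Decode molecular sequences back into SELFIES
#'
#' @param sequence Character vector of molecular sequences.
#' @param alphabet A [build_alphabet()] result.
#' @return Character vector of SELFIES strings.
#' @export
decode_sequence <- function(sequence, alphabet) {
  stopifnot(inherits(alphabet, "sequence_alphabet"))
  vapply(sequence, function(s) {
    if (!nzchar(s)) return("")
    chars <- strsplit(s, "")[[1]]
    toks <- alphabet$char_to_token[chars]
    if (anyNA(toks)) {
      stop("character(s) not in alphabet: ",
           paste(unique(chars[is.na(toks)]), collapse = ", "), call. = FALSE)
    }
    paste(toks, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Save / load an alphabet
#'
#' JSON serialisation with a format-version header; reloading is
#' bit-exact.
#'
#' @param alphabet A `sequence_alphabet`.
#' @param path File path.
#' @return `load_alphabet` returns the `sequence_alphabet`.
#' @export
save_alphabet <- function(alphabet, path) {
  stopifnot(inherits(alphabet, "sequence_alphabet"))
  jsonlite::write_json(list(format = "selfgen-alphabet", version = 1L,
                            token_to_char = as.list(alphabet$token_to_char),
                            start_char = alphabet$start_char,
                            end_char = alphabet$end_char,
                            embed = alphabet$embed),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname save_alphabet
#' @export
load_alphabet <- function(path) {
  obj <- jsonlite::read_json(path)
  if (!identical(obj$format, "selfgen-alphabet")) {
    stop("not a selfgen alphabet file: ", path, call. = FALSE)
  }
  token_to_char <- stats::setNames(unlist(obj$token_to_char),
                                   names(obj$token_to_char))
  chars <- c(obj$start_char, obj$end_char, unname(token_to_char))
  structure(list(token_to_char = token_to_char,
                 char_to_token = stats::setNames(names(token_to_char),
                                                 unname(token_to_char)),
                 chars = chars,
                 char_to_index = stats::setNames(seq_along(chars), chars),
                 start_char = obj$start_char, end_char = obj$end_char,
                 embed = as.integer(obj$embed)),
            class = "sequence_alphabet")
}

# Integer index form of padded sequences: row per molecule, `embed`
# columns: [start, sequence, end/padding...].  The model trains on this.
sequences_to_indices <- function(sequences, alphabet) {
  stopifnot(inherits(alphabet, "sequence_alphabet"))
  embed <- alphabet$embed
  end_idx <- alphabet$char_to_index[[alphabet$end_char]]
  out <- matrix(end_idx, nrow = length(sequences), ncol = embed)
  out[, 1] <- alphabet$char_to_index[[alphabet$start_char]]
  for (i in seq_along(sequences)) {
    s <- sequences[i]
    if (nchar(s) > embed - 2L) {
      stop("sequence ", i, " is longer than embed - 2 (", embed - 2L, "): ",
           nchar(s), " characters", call. = FALSE)
    }
    if (nzchar(s)) {
      idx <- alphabet$char_to_index[strsplit(s, "")[[1]]]
      if (anyNA(idx)) stop("sequence contains characters outside the alphabet",
                           call. = FALSE)
      out[i, 1 + seq_along(idx)] <- idx
    }
  }
  out
}

#' One-hot vectorisation of a molecular sequence
#'
#' Produces the `embed x alphabet_size` binary matrix for one sequence:
#' row 1 encodes the start marker `'!'`, the sequence follows, and `'E'`
#' terminates and pads to `embed`.  Every row sums to exactly 1.
#'
#' @param sequence A single molecular sequence (character scalar).
#' @param alphabet A [build_alphabet()] result.
#' @return A `onehot_sequence`: binary matrix with attribute `length`
#'   (the pre-padding sequence length); columns named by alphabet
#'   character.
#' @export
vectorize <- function(sequence, alphabet) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  idx <- sequences_to_indices(sequence, alphabet)[1, ]
  mat <- matrix(0L, nrow = alphabet$embed, ncol = length(alphabet$chars),
                dimnames = list(NULL, alphabet$chars))
  mat[cbind(seq_along(idx), idx)] <- 1L
  structure(mat, length = nchar(sequence), class = c("onehot_sequence", class(mat)))
}

#' Invert [vectorize()]
#'
#' Reads each one-hot row back to its character, strips the start marker
#' and everything from the first `'E'` on.
#'
#' @param onehot A `onehot_sequence` (or any binary matrix with one 1
#'   per row over the alphabet).
#' @param alphabet A [build_alphabet()] result.
#' @return The molecular sequence (character scalar).
#' @export
devectorize <- function(onehot, alphabet) {
  stopifnot(is.matrix(onehot), ncol(onehot) == length(alphabet$chars))
  if (!all(rowSums(onehot) == 1)) {
    stop("one-hot matrix must have exactly one 1 per row", call. = FALSE)
  }
  chars <- alphabet$chars[max.col(onehot, ties.method = "first")]
  if (chars[1] == alphabet$start_char) chars <- chars[-1]
  stop_at <- match(alphabet$end_char, chars)
  if (!is.na(stop_at)) chars <- chars[seq_len(stop_at - 1L)]
  paste(chars, collapse = "")
}
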