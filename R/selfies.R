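# SELFIES codec: a robust molecular string grammar in which every
# syntactically well-formed token string derives a valid molecule.
#
# The grammar implemented here is a self-contained dialect of the
# published SELFIES idea, covering neutral organic molecules over
# {C, N, O, S, P, F, Cl, Br, I}:
#   * atom tokens [X], [=X], [#X] request a bond of order 1/2/3 to the
#     current attachment atom, capped by both atoms' remaining valence;
#   * [Branch1]/[Branch2] open a side chain whose token length is given
#     by 1 or 2 following index symbols (length = N + 1);
#   * [Ring1]/[Ring2] (and [=Ring1], [#Ring1], [=Ring2]) close a ring to
#     the (Q+1)-th previously derived atom;
#   * tokens that cannot apply in the current derivation state are
#     skipped, which is what makes every string decodable.
# Hydrogens are implicit and follow the standard SMILES valence-fill
# convention, so the derived graph re-parses identically.

.selfies_valence <- c(C = 4L, N = 3L, O = 2L, S = 6L, P = 5L,
                      F = 1L, Cl = 1L, Br = 1L, I = 1L)

# Standard valence sets used for the implicit-hydrogen fill rule.
.selfies_std_valence <- list(C = 4L, N = 3L, O = 2L, S = c(2L, 4L, 6L),
                             P = c(3L, 5L), F = 1L, Cl = 1L, Br = 1L, I = 1L)

# 16-symbol index alphabet: index symbols double as ordinary tokens; the
# value of a token outside this list is 0.
.selfies_index_alphabet <- c("[C]", "[Ring1]", "[Ring2]", "[Branch1]",
                             "[Branch2]", "[=Ring1]", "[=C]", "[#C]",
                             "[O]", "[N]", "[=N]", "[=O]", "[S]", "[F]",
                             "[Cl]", "[Br]")

.bond_prefix_order <- function(prefix) {
  switch(prefix, "=" = 2L, "#" = 3L, 1L)
}

#' Split a SELFIES string into tokens
#'
#' @param selfies A single SELFIES string, e.g. `"[C][=C][Branch1][C][O]"`.
#' @return Character vector of bracketed tokens (length 0 for `""`).
#' @export
selfies_tokens <- function(selfies) {
  stopifnot(is.character(selfies), length(selfies) == 1, !is.na(selfies))
  if (!nzchar(selfies)) return(character(0))
  if (!grepl("^(\\[[^][]+\\])+$", selfies)) {
    stop("malformed SELFIES (must be a sequence of bracketed tokens): ",
         selfies, call. = FALSE)
  }
  regmatches(selfies, gregexpr("\\[[^][]+\\]", selfies))[[1]]
}

#' Number of SELFIES tokens
#'
#' @param selfies Character vector of SELFIES strings.
#' @return Integer vector: the number of bracketed units in each string.
#' @export
selfies_token_length <- function(selfies) {
  vapply(selfies, function(s) length(selfies_tokens(s)), integer(1),
         USE.NAMES = FALSE)
}

# Parse an atom token into list(element, order) or NULL.
.parse_atom_token <- function(token) {
  m <- regmatches(token, regexec("^\\[([=#]?)([A-Z][a-z]?)\\]$", token))[[1]]
  if (length(m) == 0) return(NULL)
  elem <- m[3]
  if (!elem %in% names(.selfies_valence)) return(NULL)
  list(element = elem, order = .bond_prefix_order(m[2]))
}

.parse_control_token <- function(token) {
  branch <- regmatches(token, regexec("^\\[Branch([12])\\]$", token))[[1]]
  if (length(branch) > 0) {
    return(list(kind = "branch", width = as.integer(branch[2])))
  }
  ring <- regmatches(token, regexec("^\\[([=#]?)Ring([12])\\]$", token))[[1]]
  if (length(ring) > 0) {
    return(list(kind = "ring", width = as.integer(ring[3]),
                order = .bond_prefix_order(ring[2])))
  }
  NULL
}

.index_value <- function(tokens) {
  vals <- match(tokens, .selfies_index_alphabet) - 1L
  vals[is.na(vals)] <- 0L
  Reduce(function(acc, v) acc * 16L + v, vals, accumulate = FALSE)
}

.index_symbols <- function(value, width) {
  digits <- integer(width)
  for (k in seq(width, 1)) {
    digits[k] <- value %% 16L
    value <- value %/% 16L
  }
  .selfies_index_alphabet[digits + 1L]
}

# --- decoding: token string -> molecular graph ------------------------------

.selfies_decode_graph <- function(tokens) {
  st <- new.env(parent = emptyenv())
  st$element <- character(0)
  st$used <- integer(0)
  st$b1 <- integer(0); st$b2 <- integer(0); st$bo <- integer(0)

  cap <- function(i) .selfies_valence[[st$element[i]]] - st$used[i]
  add_atom <- function(elem) {
    st$element <- c(st$element, elem)
    st$used <- c(st$used, 0L)
    length(st$element)
  }
  add_bond <- function(i, j, order) {
    st$b1 <- c(st$b1, i); st$b2 <- c(st$b2, j); st$bo <- c(st$bo, order)
    st$used[i] <- st$used[i] + order
    st$used[j] <- st$used[j] + order
  }
  has_bond <- function(i, j) {
    any((st$b1 == i & st$b2 == j) | (st$b1 == j & st$b2 == i))
  }

  derive <- function(lo, hi, prev) {
    i <- lo
    while (i <= hi) {
      tok <- tokens[i]
      atom <- .parse_atom_token(tok)
      if (!is.null(atom)) {
        if (prev == 0L) {
          prev <- add_atom(atom$element)
        } else {
          order <- min(atom$order, cap(prev),
                       .selfies_valence[[atom$element]])
          if (order < 1L) return(invisible(NULL))  # chain saturated: rest ignored
          new <- add_atom(atom$element)
          add_bond(prev, new, order)
          prev <- new
        }
        i <- i + 1L
        next
      }
      ctl <- .parse_control_token(tok)
      if (is.null(ctl)) {
        stop("unknown SELFIES token: ", tok, call. = FALSE)
      }
      if (i + ctl$width > hi) return(invisible(NULL))  # truncated index: stop
      q <- .index_value(tokens[(i + 1L):(i + ctl$width)])
      if (ctl$kind == "branch") {
        if (prev == 0L || cap(prev) < 2L) {
          i <- i + 1L + ctl$width  # inapplicable branch: skip header only
          next
        }
        p_lo <- i + ctl$width + 1L
        p_hi <- min(p_lo + q, hi)  # payload = q + 1 tokens, clipped
        if (p_lo <= hi) derive(p_lo, p_hi, prev)
        i <- p_hi + 1L
      } else {  # ring
        if (prev > 0L) {
          target <- max(1L, prev - (q + 1L))
          if (target != prev && !has_bond(prev, target)) {
            order <- min(ctl$order, cap(prev), cap(target))
            if (order >= 1L) add_bond(prev, target, order)
          }
        }
        i <- i + 1L + ctl$width
      }
    }
    invisible(NULL)
  }

  derive(1L, length(tokens), 0L)
  list(atoms = data.frame(element = st$element, stringsAsFactors = FALSE),
       bonds = data.frame(a1 = st$b1, a2 = st$b2, order = st$bo))
}

# --- graph -> SMILES text ---------------------------------------------------

.bond_symbol <- c("", "=", "#")

.graph_to_smiles <- function(graph) {
  n <- nrow(graph$atoms)
  if (n == 0) return("")
  adj <- rep(list(integer(0)), n)
  for (k in seq_len(nrow(graph$bonds))) {
    a <- graph$bonds$a1[k]; b <- graph$bonds$a2[k]
    adj[[a]] <- c(adj[[a]], k)
    adj[[b]] <- c(adj[[b]], k)
  }
  other <- function(k, u) {
    if (graph$bonds$a1[k] == u) graph$bonds$a2[k] else graph$bonds$a1[k]
  }

  visited <- logical(n)
  edge_used <- logical(max(nrow(graph$bonds), 1))
  closures <- rep(list(list()), n)  # per atom: list of (num, order)
  children <- rep(list(integer(0)), n)  # edge indices, in discovery order
  n_ring <- 0L

  classify <- function(u) {
    visited[u] <<- TRUE
    for (k in adj[[u]]) {
      if (edge_used[k]) next
      v <- other(k, u)
      if (!visited[v]) {
        edge_used[k] <<- TRUE
        children[[u]] <<- c(children[[u]], k)
        classify(v)
      } else {
        edge_used[k] <<- TRUE
        n_ring <<- n_ring + 1L
        num <- n_ring
        ord <- graph$bonds$order[k]
        closures[[u]] <<- c(closures[[u]], list(list(num = num, order = ord)))
        closures[[v]] <<- c(closures[[v]], list(list(num = num, order = ord)))
      }
    }
  }
  classify(1L)

  ring_digit <- function(num) if (num <= 9) as.character(num) else sprintf("%%%02d", num)

  emit <- function(u) {
    s <- graph$atoms$element[u]
    for (cl in closures[[u]]) {
      s <- paste0(s, .bond_symbol[cl$order], ring_digit(cl$num))
    }
    ks <- children[[u]]
    if (length(ks) > 0) {
      for (k in ks[-length(ks)]) {
        s <- paste0(s, "(", .bond_symbol[graph$bonds$order[k]],
                    emit(other(k, u)), ")")
      }
      k <- ks[length(ks)]
      s <- paste0(s, .bond_symbol[graph$bonds$order[k]], emit(other(k, u)))
    }
    s
  }
  emit(1L)
}

# --- encoding: graph -> token string ----------------------------------------

.expected_hcount <- function(element, bond_sum) {
  vals <- .selfies_std_valence[[element]]
  ok <- vals[vals >= bond_sum]
  if (length(ok) == 0) return(NA_integer_)
  min(ok) - bond_sum
}

.encode_graph <- function(graph, label = "") {
  atoms <- graph$atoms
  bonds <- graph$bonds
  n <- nrow(atoms)
  if (n == 0) stop("cannot encode an empty molecule", call. = FALSE)
  if (!all(atoms$element %in% names(.selfies_valence))) {
    bad <- setdiff(unique(atoms$element), names(.selfies_valence))
    stop("unsupported element(s) ", paste(bad, collapse = ", "),
         " in ", label, call. = FALSE)
  }
  if (any(atoms$charge != 0) || any(atoms$isotope != 0) || any(atoms$radical != 0)) {
    stop("charged, isotopic or radical species are not encodable: ",
         label, call. = FALSE)
  }
  bond_sum <- integer(n)
  for (k in seq_len(nrow(bonds))) {
    bond_sum[bonds$a1[k]] <- bond_sum[bonds$a1[k]] + bonds$order[k]
    bond_sum[bonds$a2[k]] <- bond_sum[bonds$a2[k]] + bonds$order[k]
  }
  if (any(bond_sum > .selfies_valence[atoms$element])) {
    stop("valence beyond the supported model in ", label, call. = FALSE)
  }
  exp_h <- mapply(.expected_hcount, atoms$element, bond_sum)
  if (any(is.na(exp_h)) || ("hs" %in% names(atoms) && any(exp_h != atoms$hs))) {
    stop("nonstandard hydrogen count is not encodable: ", label, call. = FALSE)
  }

  adj <- rep(list(integer(0)), n)
  for (k in seq_len(nrow(bonds))) {
    adj[[bonds$a1[k]]] <- c(adj[[bonds$a1[k]]], k)
    adj[[bonds$a2[k]]] <- c(adj[[bonds$a2[k]]], k)
  }
  other <- function(k, u) if (bonds$a1[k] == u) bonds$a2[k] else bonds$a1[k]

  pos <- integer(n)         # derivation order of each atom
  visited <- logical(n)
  edge_used <- logical(max(nrow(bonds), 1))
  children <- rep(list(integer(0)), n)
  back <- rep(list(list()), n)  # recorded at the later endpoint
  counter <- 0L

  classify <- function(u) {
    visited[u] <<- TRUE
    counter <<- counter + 1L
    pos[u] <<- counter
    for (k in adj[[u]]) {
      if (edge_used[k]) next
      v <- other(k, u)
      if (!visited[v]) {
        edge_used[k] <<- TRUE
        children[[u]] <<- c(children[[u]], k)
        classify(v)
      } else {
        edge_used[k] <<- TRUE
        back[[u]] <<- c(back[[u]], list(list(target = v, order = bonds$order[k])))
      }
    }
  }
  classify(1L)
  if (any(!visited)) {
    stop("disconnected molecules are not encodable: ", label, call. = FALSE)
  }

  atom_token <- function(elem, order) {
    paste0("[", c("", "=", "#")[order], elem, "]")
  }
  ring_token <- function(order, width) {
    paste0("[", c("", "=", "#")[order], "Ring", width, "]")
  }

  emit <- function(u, in_order) {
    toks <- atom_token(atoms$element[u], in_order)
    for (cl in back[[u]]) {
      q <- pos[u] - pos[cl$target] - 1L
      if (q < 16L) {
        toks <- c(toks, ring_token(cl$order, 1L), .index_symbols(q, 1L))
      } else if (q < 256L) {
        toks <- c(toks, ring_token(cl$order, 2L), .index_symbols(q, 2L))
      } else {
        stop("ring span too large to index", call. = FALSE)
      }
    }
    ks <- children[[u]]
    if (length(ks) > 0) {
      for (k in ks[-length(ks)]) {
        payload <- emit(other(k, u), bonds$order[k])
        len <- length(payload)
        if (len <= 16L) {
          toks <- c(toks, "[Branch1]", .index_symbols(len - 1L, 1L), payload)
        } else if (len <= 256L) {
          toks <- c(toks, "[Branch2]", .index_symbols(len - 1L, 2L), payload)
        } else {
          stop("branch too long to index", call. = FALSE)
        }
      }
      k <- ks[length(ks)]
      toks <- c(toks, emit(other(k, u), bonds$order[k]))
    }
    toks
  }
  paste(emit(1L, 1L), collapse = "")
}

# --- public translation ops -------------------------------------------------

#' Translate SMILES into SELFIES
#'
#' Each SMILES is canonicalised to its generic (stereo-free) form and
#' encoded as a SELFIES token string.  The encoding round-trips:
#' `selfies_to_smiles(smiles_to_selfies(s))` equals
#' `canonicalize_generic(s)`.
#'
#' @param smiles Character vector of SMILES.
#' @param strict If `TRUE` (default) unencodable molecules (charged,
#'   isotopic, exotic-valence or disconnected species) raise an error;
#'   otherwise they yield `NA`.
#' @return Character vector of SELFIES strings.
#' @export
smiles_to_selfies <- function(smiles, strict = TRUE) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0) return(character(0))
  canon <- canonicalize_generic(smiles, strict = strict)
  graphs <- mol_graph(ifelse(is.na(canon), "C", canon), strict = FALSE)
  vapply(seq_along(smiles), function(i) {
    if (is.na(canon[i]) || is.null(graphs[[i]])) return(NA_character_)
    res <- tryCatch(.encode_graph(graphs[[i]], label = smiles[i]),
                    error = function(e) if (strict) stop(e) else NA_character_)
    res
  }, character(1))
}

#' Translate SELFIES into canonical generic SMILES
#'
#' Decodes SELFIES token strings by valence-constrained derivation (any
#' well-formed token string yields a valid molecule) and canonicalises
#' the result.
#'
#' @param selfies Character vector of SELFIES strings.
#' @param canonical If `TRUE` (default) the decoded structure is
#'   canonicalised by the chemistry backend; if `FALSE` the raw Kekule
#'   SMILES text produced by the decoder is returned (no backend call).
#' @return Character vector of SMILES; `""` for token strings that
#'   derive an empty graph.
#' @export
selfies_to_smiles <- function(selfies, canonical = TRUE) {
  stopifnot(is.character(selfies))
  if (length(selfies) == 0) return(character(0))
  raw <- vapply(selfies, function(s) {
    .graph_to_smiles(.selfies_decode_graph(selfies_tokens(s)))
  }, character(1), USE.NAMES = FALSE)
  if (!canonical) return(raw)
  out <- raw
  nonempty <- nzchar(raw)
  if (any(nonempty)) {
    out[nonempty] <- canonicalize_generic(raw[nonempty])
  }
  out
}
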