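# Synthetic molecule corpora: valid, download-free training sets with
# the statistical structure the pipeline assumes (drug-like-ish token
# inventory, 30-50-token length window), plus seed-active selection and
# easy/hard sets for the synthesizability trainer.

# Tokens sampled by the corpus generator.  [=O] and [F] are valid
# tokens but are left out of the default: placed on the main chain they
# saturate the current atom and terminate derivation, which would skew
# the corpus toward tiny molecules and break the length-tracks-atoms
# structure the training window assumes.
.default_fixture_alphabet <- c("[C]", "[N]", "[O]", "[S]",
                               "[=C]", "[=N]",
                               "[Branch1]", "[Ring1]", "[Ring2]")

#' Fixture corpus settings
#'
#' @param n_molecules Number of molecules to draw.
#' @param token_alphabet SELFIES tokens sampled from (default: a
#'   drug-like-ish restricted set).
#' @param length_range Inclusive token-count interval per molecule
#'   (default `c(30, 50)`, the training-window convention).
#' @param rng_seed Seed.
#' @return Object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_molecules = 1000L,
                         token_alphabet = .default_fixture_alphabet,
                         length_range = c(30L, 50L), rng_seed = 42L) {
  stopifnot(n_molecules >= 1, length(length_range) == 2,
            length_range[1] >= 1, length_range[1] <= length_range[2])
  bad <- vapply(token_alphabet, function(t) {
    is.null(.parse_atom_token(t)) && is.null(.parse_control_token(t))
  }, logical(1))
  if (any(bad)) {
    stop("invalid SELFIES token(s) in alphabet: ",
         paste(token_alphabet[bad], collapse = ", "), call. = FALSE)
  }
  structure(list(n_molecules = as.integer(n_molecules),
                 token_alphabet = token_alphabet,
                 length_range = as.integer(length_range),
                 rng_seed = as.integer(rng_seed)),
            class = "fixture_spec")
}

#' Random SELFIES strings
#'
#' Uniform random token strings over the fixture alphabet, each starting
#' with an atom token so every string derives a non-empty molecule.
#' These are valid by construction -- the robustness property the whole
#' generative approach rests on.
#'
#' @param spec A [fixture_spec()].
#' @param n Number of strings (default `spec$n_molecules`).
#' @return Character vector of SELFIES strings.
#' @export
random_selfies <- function(spec = fixture_spec(), n = spec$n_molecules) {
  atoms <- spec$token_alphabet[!vapply(spec$token_alphabet, function(t) {
    is.null(.parse_atom_token(t))
  }, logical(1))]
  if (length(atoms) == 0) {
    stop("token alphabet contains no atom tokens", call. = FALSE)
  }
  with_seed(spec$rng_seed, {
    lens <- sample(spec$length_range[1]:spec$length_range[2], n, replace = TRUE)
    vapply(lens, function(L) {
      toks <- c(sample(atoms, 1),
                if (L > 1) sample(spec$token_alphabet, L - 1, replace = TRUE))
      paste(toks, collapse = "")
    }, character(1))
  })
}

#' Random synthetic corpus
#'
#' Draws random SELFIES token strings (each valid by construction),
#' decodes them to molecules, canonicalises, re-encodes to the
#' molecule's canonical SELFIES and keeps those whose token count falls
#' in the requested window, deduplicated on canonical generic SMILES.
#' Random derivations often terminate before their token budget is
#' spent, so raw strings are drawn longer than the window and
#' rejection-sampled; the resulting records have `token_length`
#' faithful to molecule size, mirroring the structure of a real
#' length-filtered training set.  The token-length histogram is
#' attached.
#'
#' @param spec A [fixture_spec()]; `length_range` bounds the records'
#'   token counts.
#' @return Molecule records data frame (`smiles_raw` -- the decoder's
#'   SMILES text, `smiles_generic`, `selfies`, `token_length`,
#'   `source_tag = "synthetic"`), with attribute `length_histogram`.
#' @export
random_corpus <- function(spec = fixture_spec()) {
  lo <- spec$length_range[1]; hi <- spec$length_range[2]
  acc <- NULL
  with_seed(spec$rng_seed, {
    for (round in seq_len(50)) {
      need <- spec$n_molecules - NROW(acc)
      if (need <= 0) break
      draw_spec <- spec
      draw_spec$length_range <- c(2L * lo, ceiling(2.6 * hi))
      draw_spec$rng_seed <- sample.int(.Machine$integer.max, 1)
      draw_spec$n_molecules <- max(50L, 5L * need)
      raw_selfies <- random_selfies(draw_spec)
      raw_smiles <- selfies_to_smiles(raw_selfies, canonical = FALSE)
      generic <- canonicalize_generic(raw_smiles)
      selfies <- smiles_to_selfies(generic, strict = FALSE)
      tl <- rep(0L, length(selfies))
      ok <- !is.na(selfies)
      tl[ok] <- selfies_token_length(selfies[ok])
      keep <- ok & tl >= lo & tl <= hi
      batch <- data.frame(smiles_raw = raw_smiles[keep],
                          smiles_generic = generic[keep],
                          selfies = selfies[keep],
                          token_length = tl[keep],
                          source_tag = "synthetic",
                          stringsAsFactors = FALSE)
      acc <- rbind(acc, batch)
      acc <- acc[!duplicated(acc$smiles_generic), , drop = FALSE]
    }
  })
  if (NROW(acc) < spec$n_molecules) {
    stop("could not draw ", spec$n_molecules, " unique molecules in the ",
         "requested length window; got ", NROW(acc), call. = FALSE)
  }
  out <- acc[seq_len(spec$n_molecules), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "length_histogram") <- table(out$token_length)
  out
}

#' Select seed actives from a scored corpus
#'
#' Applies the two-from-the-top, two-from-the-middle, one-last selection
#' rule to a descending composite-score ranking ("middle" read as the
#' two central ranks).  For other `n`, the last rank is always taken
#' (when `n >= 3`) and the remainder is split top-heavy between top and
#' middle; `n = 1` returns the top-ranked molecule.
#'
#' @param scored A [normalize_and_rank()] result (sorted descending by
#'   `my_score`).
#' @param n Number of seeds (default 5).
#' @return The selected rows of `scored`, with a `rank` column.
#' @export
make_seed_actives <- function(scored, n = 5L) {
  stopifnot(is.data.frame(scored), "my_score" %in% names(scored), n >= 1)
  m <- nrow(scored)
  if (m < n) stop("scored corpus (", m, ") smaller than n = ", n, call. = FALSE)
  if (n == 1) {
    ranks <- 1L
  } else {
    k_last <- if (n >= 3) 1L else 0L
    k_top <- as.integer(ceiling((n - k_last) / 2))
    k_mid <- n - k_last - k_top
    mid_start <- as.integer(floor((m - k_mid) / 2) + 1)
    ranks <- unique(c(seq_len(k_top),
                      if (k_mid > 0) seq(mid_start, length.out = k_mid),
                      if (k_last > 0) m))
    ranks <- as.integer(ranks)
  }
  out <- scored[ranks, , drop = FALSE]
  out$rank <- ranks
  rownames(out) <- NULL
  out
}

# Programmatic easy set: short chains and simple monocycles over common
# functional groups.
.easy_pool <- function() {
  chains <- vapply(2:10, function(n) strrep("C", n), character(1))
  c(chains,
    paste0(chains, "O"),                      # alcohols
    paste0(chains, "N"),                      # amines
    paste0("CC(=O)O", c("C", "CC", "CCC")),   # esters
    "CC(=O)C", "CCOC", "CCOCC", "CC(C)O", "CC(C)C", "CC(N)C(=O)O",
    "c1ccccc1", "Cc1ccccc1", "Oc1ccccc1", "Nc1ccccc1", "CCc1ccccc1",
    "C1CCCCC1", "C1CCCC1", "C1CCOC1", "C1CCNC1", "O=C(C)Nc1ccccc1")
}

# Hard set: fused/caged/spiro polycyclics with dense ring systems.
.hard_pool <- function() {
  c("C1C2CC3CC1CC(C2)C3",                         # adamantane
    "C12C3C4C1C5C2C3C45",                         # cubane
    "C1CC2(CC1)CCC1(CC2)CCCC1",                   # dispiro system
    "C1CC2CC1C1CC3CC(C1)C2C3",
    "C1C2CC3C1C1CC(C2)C31",
    "C1CC2CCC1C1C2C2CCC1CC2",
    "C1C2CC3CC1C1C2C3C1",
    "C12CC3CC(C1)C1CC2CC3C1",
    "C1CC23CC1(CC2)CCC3",
    "C1C2C3C4C1C1C2C3C41",
    "C1CC2(CCC1CC1CCC3(CC1)CCCC3)CCCC2",
    "C1C2C3C1C1C2C31",
    "C12C3C1C1C4C2C3C14",
    "C1CC2CC3(C1)CC1CC(C3)CC2C1",
    "C1C2CC3(C1)CC1(C2)CC2(C3)CC3(C1)CC12CC3C1")
}

#' Easy/hard training sets for the synthesizability score
#'
#' Draws disjoint sets of simple (chains, single rings) and complex
#' (fused, caged, spiro polycyclic) molecules from bundled pools,
#' canonicalised and deduplicated; used to train the Bernoulli fragment
#' table.
#'
#' @param n_each Molecules per set (capped by the pool sizes).
#' @param rng_seed Seed for the draw.
#' @return List with character vectors `easy` and `hard` (canonical
#'   generic SMILES, disjoint).
#' @export
make_easy_hard_sets <- function(n_each = 15L, rng_seed = 42L) {
  easy <- canonicalize_generic(.easy_pool())
  hard <- canonicalize_generic(.hard_pool())
  easy <- setdiff(unique(easy), hard)
  hard <- unique(hard)
  with_seed(rng_seed, {
    list(easy = sample(easy, min(n_each, length(easy))),
         hard = sample(hard, min(n_each, length(hard))))
  })
}
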