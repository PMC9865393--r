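# Candidate generation by latent-space perturbation ("tensor scaling"):
# noise of a given amplitude is added to the latent state of each seed
# active, the perturbed state is decoded greedily, and the resulting
# SELFIES are translated to canonical SMILES and deduplicated.

#' Generation settings
#'
#' @param amplitudes Noise amplitudes to sample at (default `c(0.1, 0.2)`).
#' @param samples_per_seed Decoded samples per seed molecule per
#'   amplitude (default 20).
#' @param noise One of `"gaussian"` (default; per-component standard
#'   deviation equal to the amplitude) or `"uniform"` (uniform on
#'   `[-amplitude, amplitude]`).
#' @param rng_seed Seed for the noise draws.
#' @return Object of class `generation_spec`.
#' @export
generation_spec <- function(amplitudes = c(0.1, 0.2), samples_per_seed = 20L,
                            noise = c("gaussian", "uniform"), rng_seed = 42L) {
  noise <- match.arg(noise)
  stopifnot(is.numeric(amplitudes), all(amplitudes >= 0),
            samples_per_seed >= 1)
  structure(list(amplitudes = amplitudes,
                 samples_per_seed = as.integer(samples_per_seed),
                 noise = noise, rng_seed = as.integer(rng_seed)),
            class = "generation_spec")
}

#' Perturb a latent state
#'
#' Adds independent zero-mean noise of the given amplitude to every
#' component of both the hidden and the cell vector.  Amplitude 0
#' returns the state unchanged.
#'
#' @param state A `latent_state`.
#' @param amplitude Non-negative noise scale.
#' @param noise `"gaussian"` or `"uniform"` (see [generation_spec()]).
#' @return A perturbed `latent_state`.
#' @export
perturb_latent <- function(state, amplitude, noise = "gaussian") {
  stopifnot(inherits(state, "latent_state"), amplitude >= 0)
  if (amplitude == 0) return(state)
  n <- length(state$h) + length(state$c)
  eps <- switch(noise,
                gaussian = stats::rnorm(n, 0, amplitude),
                uniform = stats::runif(n, -amplitude, amplitude),
                stop("unknown noise distribution: ", noise, call. = FALSE))
  structure(list(h = state$h + eps[seq_along(state$h)],
                 c = state$c + eps[length(state$h) + seq_along(state$c)]),
            class = "latent_state")
}

#' Generate candidate molecules around seed actives
#'
#' For every seed and amplitude, draws `samples_per_seed` perturbed
#' latent states, decodes each greedily, maps the molecular sequence
#' back through SELFIES to canonical generic SMILES, and deduplicates:
#' first within each amplitude, then across amplitudes.  Seed molecules
#' may legitimately reappear among the candidates.
#'
#' @param seeds Character vector of seed SMILES (encodable molecules).
#' @param model A trained [train_seq2seq()] model.
#' @param alphabet The model's alphabet.
#' @param spec A [generation_spec()].
#' @return List with data frames:
#'   `raw` (every decoded sample: seed_id, amplitude, sample, selfies,
#'   smiles, valid), `unique_by_amplitude` (deduplicated on canonical
#'   SMILES within amplitude) and `unique` (merged across amplitudes).
#' @export
generate_candidates <- function(seeds, model, alphabet,
                                spec = generation_spec()) {
  stopifnot(is.character(seeds), length(seeds) >= 1,
            inherits(spec, "generation_spec"))
  seed_selfies <- smiles_to_selfies(seeds)
  seed_sequences <- encode_sequence(seed_selfies, alphabet)
  states <- encode_latent(model, seed_sequences, alphabet)

  rows <- with_seed(spec$rng_seed, {
    out <- list()
    for (a in spec$amplitudes) {
      for (i in seq_along(seeds)) {
        for (k in seq_len(spec$samples_per_seed)) {
          st <- perturb_latent(states[[i]], a, spec$noise)
          seqc <- decode_states(model, st, alphabet)
          out[[length(out) + 1L]] <- data.frame(
            seed_id = i, amplitude = a, sample = k,
            sequence = seqc, stringsAsFactors = FALSE)
        }
      }
    }
    do.call(rbind, out)
  })

  rows$selfies <- decode_sequence(rows$sequence, alphabet)
  smiles_raw <- selfies_to_smiles(rows$selfies, canonical = FALSE)
  rows$smiles <- NA_character_
  nonempty <- nzchar(smiles_raw)
  if (any(nonempty)) {
    rows$smiles[nonempty] <- canonicalize_generic(smiles_raw[nonempty],
                                                  strict = FALSE)
  }
  rows$valid <- !is.na(rows$smiles) & nzchar(rows$smiles)

  raw <- rows[, c("seed_id", "amplitude", "sample", "selfies", "smiles", "valid")]
  ok <- raw[raw$valid, , drop = FALSE]
  by_amp <- do.call(rbind, lapply(split(ok, ok$amplitude), function(d) {
    d[!duplicated(d$smiles), , drop = FALSE]
  }))
  rownames(by_amp) <- NULL
  merged <- by_amp[!duplicated(by_amp$smiles), , drop = FALSE]
  rownames(merged) <- NULL
  list(raw = raw, unique_by_amplitude = by_amp, unique = merged)
}

#' Annotate candidates with PubChem CIDs
#'
#' Looks each canonical SMILES up in PubChem's PUG REST service and
#' records the CID where one exists.  This is annotation only -- it
#' never filters.  Without network access (the default situation in
#' batch environments) the candidates are returned unchanged with a
#' warning.
#'
#' @param candidates Data frame with a `smiles` column.
#' @param enabled Attempt network lookups (default
#'   `getOption("selfgen.pubchem", FALSE)`).
#' @return `candidates` with a `pubchem_cid` column (`NA` where not
#'   found or not looked up).
#' @export
lookup_pubchem <- function(candidates,
                           enabled = getOption("selfgen.pubchem", FALSE)) {
  stopifnot(is.data.frame(candidates), "smiles" %in% names(candidates))
  candidates$pubchem_cid <- NA_integer_
  if (!isTRUE(enabled)) {
    warning("PubChem lookup skipped (no network access configured); ",
            "candidates left unannotated", call. = FALSE)
    return(candidates)
  }
  for (i in seq_len(nrow(candidates))) {
    cid <- tryCatch({
      url <- paste0("https://pubchem.ncbi.nlm.nih.gov/rest/pug/compound/smiles/",
                    utils::URLencode(candidates$smiles[i], reserved = TRUE),
                    "/cids/JSON")
      res <- jsonlite::fromJSON(url)
      as.integer(res$IdentifierList$CID[1])
    }, error = function(e) NA_integer_)
    candidates$pubchem_cid[i] <- cid
  }
  candidates
}
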