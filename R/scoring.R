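# Drug-likeness scoring and the three-stage discriminator cascade:
# QED >= 0.5, Lipinski's rule of 5, and a Bernoulli circular-fragment
# synthesizability score with threshold 0; plus min-max normalisation
# and the composite "my score" ranking.

#' Descriptor panel
#'
#' Computes, per molecule: molecular weight (g/mol), Crippen logP,
#' H-bond donor and acceptor counts (Lipinski N+O convention) and the
#' QED drug-likeness estimate, via the descriptor engine.
#'
#' @param smiles Character vector of valid SMILES.
#' @return Data frame: `smiles`, `mw`, `logp`, `hbd`, `hba`, `qed`.
#' @export
compute_panel <- function(smiles) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  resp <- chem_call("panel", smiles = I(smiles))
  .chem_check_errors(smiles, resp$error, strict = TRUE)
  out <- do.call(rbind, lapply(resp$result, function(p) {
    data.frame(mw = p$mw, logp = p$logp, hbd = p$hbd, hba = p$hba,
               qed = p$qed)
  }))
  cbind(data.frame(smiles = smiles, stringsAsFactors = FALSE), out)
}

#' Lipinski rule-of-5 check
#'
#' Passes molecules with MW <= 500, logP <= 5, donors <= 5 and
#' acceptors <= 10 (boundary values pass).  By default zero violations
#' are allowed; `max_violations = 1` gives the classic relaxed variant.
#'
#' @param panel Data frame from [compute_panel()].
#' @param max_violations Number of tolerated violations (default 0).
#' @return Logical vector.
#' @export
ro5_pass <- function(panel, max_violations = 0L) {
  stopifnot(all(c("mw", "logp", "hbd", "hba") %in% names(panel)))
  violations <- (panel$mw > 500) + (panel$logp > 5) +
    (panel$hbd > 5) + (panel$hba > 10)
  violations <= max_violations
}

#' Train a Bernoulli fragment table for synthesizability scoring
#'
#' For every circular fragment observed in the training sets, the table
#' stores the smoothed Bernoulli log-likelihood ratio
#' `ln((n_easy + p) / (N_easy + 2p)) - ln((n_hard + p) / (N_hard + 2p))`,
#' where `n_*` counts molecules containing the fragment, `N_*` the set
#' sizes and `p` the pseudocount.  Fragments never seen in training
#' contribute the corresponding unseen-fragment value when scoring.
#'
#' @param easy_smiles,hard_smiles Non-empty sets of easy- and
#'   hard-to-synthesize molecules.
#' @param pseudocount Smoothing pseudocount `p` (default 1).
#' @param radius Circular fragment radius (default 2).
#' @return Object of class `fragment_table`.
#' @export
train_fragment_table <- function(easy_smiles, hard_smiles, pseudocount = 1,
                                 radius = 2) {
  stopifnot(length(easy_smiles) >= 1, length(hard_smiles) >= 1,
            pseudocount > 0)
  frags_easy <- mol_fragments(easy_smiles, radius = radius)
  frags_hard <- mol_fragments(hard_smiles, radius = radius)
  n_easy <- length(easy_smiles)
  n_hard <- length(hard_smiles)
  count_easy <- table(unlist(lapply(frags_easy, unique)))
  count_hard <- table(unlist(lapply(frags_hard, unique)))
  all_frags <- union(names(count_easy), names(count_hard))
  ne <- as.numeric(count_easy[all_frags]); ne[is.na(ne)] <- 0
  nh <- as.numeric(count_hard[all_frags]); nh[is.na(nh)] <- 0
  p <- pseudocount
  values <- log((ne + p) / (n_easy + 2 * p)) - log((nh + p) / (n_hard + 2 * p))
  unseen <- log(p / (n_easy + 2 * p)) - log(p / (n_hard + 2 * p))
  structure(list(values = stats::setNames(values, all_frags),
                 unseen = unseen, pseudocount = p, radius = radius,
                 n_easy = n_easy, n_hard = n_hard),
            class = "fragment_table")
}

#' @export
print.fragment_table <- function(x, ...) {
  cat("<fragment_table>", length(x$values), "fragments (radius", x$radius,
      "), pseudocount", x$pseudocount, "\n")
  invisible(x)
}

#' Synthesizability score
#'
#' Sum, over the distinct circular fragments of each molecule, of the
#' table's log-likelihood-ratio contributions.  Higher means easier to
#' synthesize; the cascade threshold is 0.  A molecule with no
#' fragments scores 0.
#'
#' @param smiles Character vector of valid SMILES.
#' @param table A [train_fragment_table()] result.
#' @return Numeric vector of scores.
#' @export
syn_score <- function(smiles, table) {
  stopifnot(inherits(table, "fragment_table"))
  frag_sets <- mol_fragments(smiles, radius = table$radius)
  vapply(frag_sets, function(fs) {
    fs <- unique(fs)
    if (length(fs) == 0) return(0)
    vals <- table$values[fs]
    vals[is.na(vals)] <- table$unseen
    sum(vals)
  }, numeric(1))
}

#' Save / load a fragment table
#'
#' Two-column CSV (`fragment_id`, `value`) plus a JSON header with the
#' radius, pseudocount, set sizes and unseen-fragment value; reloading
#' is bit-exact.
#'
#' @param table A `fragment_table`.
#' @param csv_path,header_path Output paths.
#' @export
save_fragment_table <- function(table, csv_path, header_path) {
  stopifnot(inherits(table, "fragment_table"))
  utils::write.csv(data.frame(fragment_id = names(table$values),
                              value = sprintf("%.17g", unname(table$values))),
                   csv_path, row.names = FALSE, quote = FALSE)
  jsonlite::write_json(list(format = "selfgen-fragment-table", version = 1L,
                            radius = table$radius,
                            pseudocount = table$pseudocount,
                            n_easy = table$n_easy, n_hard = table$n_hard,
                            unseen = sprintf("%.17g", table$unseen)),
                       header_path, auto_unbox = TRUE)
  invisible(csv_path)
}

#' @rdname save_fragment_table
#' @export
load_fragment_table <- function(csv_path, header_path) {
  hdr <- jsonlite::read_json(header_path)
  if (!identical(hdr$format, "selfgen-fragment-table")) {
    stop("not a selfgen fragment table header: ", header_path, call. = FALSE)
  }
  df <- utils::read.csv(csv_path, colClasses = c("character", "character"))
  structure(list(values = stats::setNames(as.numeric(df$value), df$fragment_id),
                 unseen = as.numeric(hdr$unseen),
                 pseudocount = hdr$pseudocount, radius = hdr$radius,
                 n_easy = hdr$n_easy, n_hard = hdr$n_hard),
            class = "fragment_table")
}

#' Min-max normalisation over a reference set
#'
#' Maps `x` onto `[0, 1]` relative to the minimum and maximum of the
#' reference values: the reference maximum maps to 1, the minimum to 0.
#' Values outside the reference range are clipped.  A constant
#' reference is degenerate and raises an error, except for a single
#' value, which normalises to 0 by convention.
#'
#' @param x Numeric vector to normalise.
#' @param reference Numeric reference values (default `x` itself).
#' @return Numeric vector in `[0, 1]`.
#' @export
minmax_norm <- function(x, reference = x) {
  lo <- min(reference); hi <- max(reference)
  if (hi == lo) {
    if (length(x) == 1) return(0)  # single-candidate convention
    stop("degenerate normalisation: constant reference values", call. = FALSE)
  }
  pmin(1, pmax(0, (x - lo) / (hi - lo)))
}

#' Score candidates: panels, flags, normalisation and composite ranking
#'
#' Computes the descriptor panel and synthesizability score for each
#' candidate, min-max normalises QED and the synthesizability score
#' over a stated reference set, and ranks by the composite
#' `my_score = 100 * (qed_norm + syn_norm) / 2`, sorted descending.
#' Normalised values are clipped to `[0, 1]` when a candidate falls
#' outside the reference range; every result records which reference
#' set was used.
#'
#' @param smiles Character vector of candidate SMILES.
#' @param table A [train_fragment_table()] result.
#' @param reference Optional data frame with `qed` and `syn_score`
#'   columns defining the normalisation reference set; default: the
#'   candidates themselves.
#' @param max_violations Passed to [ro5_pass()].
#' @return Data frame (class `score_cards`) sorted descending by
#'   `my_score`: panel columns, `syn_score`, `qed_norm`, `syn_norm`,
#'   `my_score`, `passed_qed`, `passed_ro5`, `passed_syn`; attribute
#'   `reference` names the reference set.
#' @export
normalize_and_rank <- function(smiles, table, reference = NULL,
                               max_violations = 0L) {
  panel <- compute_panel(smiles)
  panel$syn_score <- syn_score(smiles, table)
  ref <- reference %||% panel
  stopifnot(all(c("qed", "syn_score") %in% names(ref)))
  panel$qed_norm <- minmax_norm(panel$qed, ref$qed)
  panel$syn_norm <- minmax_norm(panel$syn_score, ref$syn_score)
  panel$my_score <- 100 * (panel$qed_norm + panel$syn_norm) / 2
  panel$passed_qed <- panel$qed >= 0.5
  panel$passed_ro5 <- ro5_pass(panel, max_violations)
  panel$passed_syn <- panel$syn_score >= 0
  panel <- panel[order(-panel$my_score), , drop = FALSE]
  rownames(panel) <- NULL
  attr(panel, "reference") <- if (is.null(reference)) "candidates" else "external"
  class(panel) <- c("score_cards", class(panel))
  panel
}

#' Discriminator cascade
#'
#' Applies the three filters in order -- QED >= 0.5, rule of 5,
#' synthesizability score >= 0 (exact zero is retained) -- and reports
#' per-stage marginal counts, the pairwise and full conjunctions, and
#' the QED-and-Ro5 pass percentage.
#'
#' @param cards A [normalize_and_rank()] result (or any data frame with
#'   `passed_qed`, `passed_ro5`, `passed_syn`).
#' @return List with `survivors` (rows passing all three stages) and
#'   `counts`: `input`, `pass_qed`, `pass_ro5`, `pass_syn`,
#'   `qed_and_ro5`, `all`, `pct_qed_ro5`, `pct_all`.
#' @export
filter_cascade <- function(cards) {
  stopifnot(all(c("passed_qed", "passed_ro5", "passed_syn") %in% names(cards)))
  n <- nrow(cards)
  both <- cards$passed_qed & cards$passed_ro5
  all3 <- both & cards$passed_syn
  survivors <- cards[all3, , drop = FALSE]
  rownames(survivors) <- NULL
  list(survivors = survivors,
       counts = c(input = n,
                  pass_qed = sum(cards$passed_qed),
                  pass_ro5 = sum(cards$passed_ro5),
                  pass_syn = sum(cards$passed_syn),
                  qed_and_ro5 = sum(both),
                  all = sum(all3),
                  pct_qed_ro5 = round(100 * sum(both) / n, 2),
                  pct_all = round(100 * sum(all3) / n, 2)))
}
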