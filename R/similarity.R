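# Fingerprint-based Tanimoto similarity: novelty audit of generated
# candidates against seeds and training molecules.

#' Path-based molecular fingerprints
#'
#' Daylight-like hashed path fingerprints (the descriptor engine's
#' "RDKit fingerprint"): paths up to `max_path` bonds hashed onto
#' `n_bits` positions.
#'
#' @param smiles Character vector of valid SMILES.
#' @param n_bits Fingerprint length in bits (default 2048).
#' @param max_path Maximum path length in bonds (default 7).
#' @return A list of `fingerprint` objects (`bits`: sorted 0-based
#'   positions of set bits; `n_bits`).
#' @export
fingerprint <- function(smiles, n_bits = 2048L, max_path = 7L) {
  bitsets <- chem_fingerprint_bits(smiles, n_bits = n_bits,
                                   max_path = max_path, strict = TRUE)
  lapply(bitsets, function(b) {
    structure(list(bits = b, n_bits = as.integer(n_bits)),
              class = "fingerprint")
  })
}

#' Tanimoto similarity coefficient
#'
#' `|a intersect b| / |a union b|` over the set bits of two equal-length
#' fingerprints.  1 means identical bit representations, 0 means no
#' common components; two all-zero fingerprints are identical by
#' convention (1).
#'
#' @param a,b `fingerprint` objects with equal `n_bits`.
#' @return Similarity in `[0, 1]`.
#' @export
tanimoto <- function(a, b) {
  stopifnot(inherits(a, "fingerprint"), inherits(b, "fingerprint"))
  if (a$n_bits != b$n_bits) {
    stop("fingerprint lengths differ: ", a$n_bits, " vs ", b$n_bits,
         call. = FALSE)
  }
  n_union <- length(union(a$bits, b$bits))
  if (n_union == 0) return(1)
  length(intersect(a$bits, b$bits)) / n_union
}

#' Pairwise similarity report
#'
#' Tanimoto similarities for every ordered pair of set A x set B, with
#' summary statistics and histogram bin counts for plotting.
#'
#' @param smiles_a,smiles_b Non-empty character vectors of SMILES.
#' @param n_bits,max_path Fingerprint parameters (see [fingerprint()]).
#' @param bin_width Histogram bin width on `[0, 1]` (default 0.05).
#' @return List: `matrix` (|A| x |B|, dimnames from the inputs),
#'   `summary` (`min`, `mean`, `max`), `histogram` (data frame:
#'   `bin_lo`, `bin_hi`, `count`).
#' @export
similarity_report <- function(smiles_a, smiles_b, n_bits = 2048L,
                              max_path = 7L, bin_width = 0.05) {
  stopifnot(length(smiles_a) >= 1, length(smiles_b) >= 1)
  pool <- unique(c(smiles_a, smiles_b))
  fps <- fingerprint(pool, n_bits = n_bits, max_path = max_path)
  names(fps) <- pool
  mat <- matrix(NA_real_, length(smiles_a), length(smiles_b),
                dimnames = list(smiles_a, smiles_b))
  for (i in seq_along(smiles_a)) {
    for (j in seq_along(smiles_b)) {
      mat[i, j] <- tanimoto(fps[[smiles_a[i]]], fps[[smiles_b[j]]])
    }
  }
  breaks <- seq(0, 1, by = bin_width)
  if (breaks[length(breaks)] < 1) breaks <- c(breaks, 1)
  counts <- as.vector(table(cut(as.vector(mat), breaks = breaks,
                                include.lowest = TRUE, right = FALSE)))
  list(matrix = mat,
       summary = c(min = min(mat), mean = mean(mat), max = max(mat)),
       histogram = data.frame(bin_lo = breaks[-length(breaks)],
                              bin_hi = breaks[-1],
                              count = counts))
}

#' Write a similarity report to disk
#'
#' CSV matrix, JSON summary and CSV histogram bins under a common
#' prefix: `<prefix>_matrix.csv`, `<prefix>_summary.json`,
#' `<prefix>_histogram.csv`.
#'
#' @param report A [similarity_report()] result.
#' @param prefix Output path prefix.
#' @return The three paths, invisibly.
#' @export
write_similarity_report <- function(report, prefix) {
  stopifnot(all(c("matrix", "summary", "histogram") %in% names(report)))
  paths <- paste0(prefix, c("_matrix.csv", "_summary.json", "_histogram.csv"))
  utils::write.csv(report$matrix, paths[1])
  jsonlite::write_json(as.list(report$summary), paths[2],
                       auto_unbox = TRUE, digits = NA)
  utils::write.csv(report$histogram, paths[3], row.names = FALSE)
  invisible(paths)
}
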