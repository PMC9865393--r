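# Interface to the RDKit descriptor engine (bundled python helper).
# Every wrapper is vectorised over molecules: one subprocess per call,
# whole corpora per request.

selfgen_python <- function() {
  py <- getOption("selfgen.python", "")
  if (!nzchar(py)) py <- Sys.getenv("SELFGEN_PYTHON", "")
  if (!nzchar(py)) py <- Sys.which("python")
  if (!nzchar(py)) py <- Sys.which("python3")
  if (!nzchar(py)) {
    stop("No python interpreter found; set options(selfgen.python=...) or SELFGEN_PYTHON.",
         call. = FALSE)
  }
  py
}

chemtool_path <- function() {
  path <- system.file("python", "chemtool.py", package = "selfgen")
  if (!nzchar(path)) stop("chemtool.py not found; is selfgen installed?", call. = FALSE)
  path
}

#' @keywords internal
chem_call <- function(op, ...) {
  req <- jsonlite::toJSON(c(list(op = op), list(...)), auto_unbox = TRUE, null = "null")
  out <- suppressWarnings(system2(selfgen_python(), shQuote(chemtool_path()),
                                  input = req, stdout = TRUE, stderr = FALSE))
  status <- attr(out, "status")
  if (!is.null(status) && status != 0 && length(out) == 0) {
    stop("chemistry backend failed (exit ", status, ")", call. = FALSE)
  }
  resp <- jsonlite::fromJSON(paste(out, collapse = ""), simplifyVector = FALSE)
  if (!isTRUE(resp$ok)) {
    stop("chemistry backend error: ", resp$message, call. = FALSE)
  }
  resp
}

# Raise a parse error naming every offending input, or return NULL.
.chem_check_errors <- function(smiles, errors, strict) {
  bad <- !vapply(errors, is.null, logical(1))
  if (any(bad) && strict) {
    stop("chemistry backend could not process: ",
         paste(sprintf("%s (%s)", smiles[bad],
                       vapply(errors[bad], identity, character(1))),
               collapse = "; "),
         call. = FALSE)
  }
  bad
}

#' Canonical generic SMILES
#'
#' Canonicalises SMILES with all stereochemistry (tetrahedral centres and
#' double-bond geometry) removed, so that a chiral molecule and its
#' enantiomer map to the same string.  The generic form shrinks the
#' character set the downstream sequence model has to learn.
#'
#' @param smiles Character vector of SMILES strings.
#' @param strict If `TRUE` (default), unparsable input raises an error
#'   naming the offending string; otherwise it yields `NA`.
#' @return Character vector of canonical generic SMILES (idempotent:
#'   re-canonicalising the output returns it unchanged).
#' @examples
#' \dontrun{
#' canonicalize_generic(c("C[C@@H](N)C(=O)O", "C[C@@H](N)C(=O)O"))
#' }
#' @export
canonicalize_generic <- function(smiles, strict = TRUE) {
  stopifnot(is.character(smiles))
  if (length(smiles) == 0) return(character(0))
  resp <- chem_call("canonical", smiles = I(smiles))
  bad <- .chem_check_errors(smiles, resp$error, strict)
  out <- rep(NA_character_, length(smiles))
  out[!bad] <- vapply(resp$result[!bad], identity, character(1))
  out
}

#' Heavy-atom molecular graph
#'
#' Parses SMILES into a kekulized, hydrogen-suppressed graph: a data frame
#' of atoms (element, formal charge, isotope, radical electrons) and a
#' data frame of bonds (1-based atom indices, integer bond order).
#'
#' @inheritParams canonicalize_generic
#' @return A list (one element per molecule) of `list(atoms=, bonds=)`;
#'   `NULL` for failures when `strict = FALSE`.
#' @export
mol_graph <- function(smiles, strict = TRUE) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  resp <- chem_call("graph", smiles = I(smiles))
  bad <- .chem_check_errors(smiles, resp$error, strict)
  lapply(seq_along(smiles), function(i) {
    if (bad[i]) return(NULL)
    g <- resp$result[[i]]
    atoms <- do.call(rbind, lapply(g$atoms, function(a) {
      data.frame(element = a$element, charge = a$charge,
                 isotope = a$isotope, radical = a$radical, hs = a$hs,
                 stringsAsFactors = FALSE)
    }))
    if (length(g$bonds) > 0) {
      bonds <- do.call(rbind, lapply(g$bonds, function(b) {
        data.frame(a1 = b$a1, a2 = b$a2, order = b$order)
      }))
    } else {
      bonds <- data.frame(a1 = integer(0), a2 = integer(0), order = integer(0))
    }
    list(atoms = atoms, bonds = bonds)
  })
}

#' @keywords internal
chem_fingerprint_bits <- function(smiles, n_bits = 2048, max_path = 7, strict = TRUE) {
  resp <- chem_call("fingerprint", smiles = I(smiles), n_bits = n_bits, max_path = max_path)
  bad <- .chem_check_errors(smiles, resp$error, strict)
  lapply(seq_along(smiles), function(i) {
    if (bad[i]) return(NULL)
    as.integer(unlist(resp$result[[i]], use.names = FALSE))
  })
}

#' Circular fragment identifiers
#'
#' Distinct hashed circular-fragment (Morgan atom environment) identifiers
#' present in each molecule, up to the given radius.  These are the
#' features of the Bernoulli synthesizability score
#' ([train_fragment_table()], [syn_score()]).
#'
#' @inheritParams canonicalize_generic
#' @param radius Maximum fragment radius in bonds (default 2).
#' @return List of character vectors of fragment identifiers.
#' @export
mol_fragments <- function(smiles, radius = 2, strict = TRUE) {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  resp <- chem_call("fragments", smiles = I(smiles), radius = radius)
  bad <- .chem_check_errors(smiles, resp$error, strict)
  lapply(seq_along(smiles), function(i) {
    if (bad[i]) return(NULL)
    vapply(resp$result[[i]], identity, character(1))
  })
}
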