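# Corpus preparation: raw SMILES -> deduplicated, length- and
# element-filtered SELFIES training records, plus the train/validation
# split.

#' Corpus preparation settings
#'
#' @param length_min,length_max Inclusive SELFIES token-length window for
#'   training molecules (defaults 30 and 50).
#' @param allowed_elements Elements a training molecule may contain
#'   (implicit hydrogens included).  Molecules with anything else --
#'   rare heteroatoms such as Sn, Se, B or P -- are removed.
#' @param validation_fraction Fraction of records held out for
#'   validation (default 0.10).
#' @param rng_seed Seed for the split.
#' @return An object of class `corpus_spec`.
#' @export
corpus_spec <- function(length_min = 30L, length_max = 50L,
                        allowed_elements = c("H", "C", "N", "O", "S",
                                             "F", "Cl", "Br", "I"),
                        validation_fraction = 0.10, rng_seed = 42L) {
  stopifnot(length_min >= 1, length_min <= length_max,
            validation_fraction > 0, validation_fraction < 1,
            is.character(allowed_elements), length(allowed_elements) >= 1)
  structure(list(length_min = as.integer(length_min),
                 length_max = as.integer(length_max),
                 allowed_elements = allowed_elements,
                 validation_fraction = validation_fraction,
                 rng_seed = as.integer(rng_seed)),
            class = "corpus_spec")
}

# Elements present in a SELFIES string (from its atom tokens), plus "H"
# for the implicit hydrogens.
.selfies_elements <- function(selfies) {
  toks <- selfies_tokens(selfies)
  elems <- vapply(toks, function(t) {
    a <- .parse_atom_token(t)
    if (is.null(a)) NA_character_ else a$element
  }, character(1), USE.NAMES = FALSE)
  unique(c("H", elems[!is.na(elems)]))
}

#' Build molecule records from raw SMILES
#'
#' Canonicalises each SMILES to its generic form, translates it into
#' SELFIES and counts the tokens.  Molecules that cannot be processed
#' (unparsable, charged, exotic valence) are dropped with a message;
#' the number dropped is attached as attribute `n_dropped`.
#'
#' @param smiles Character vector of raw SMILES.
#' @param source_tag Provenance label stored with each record.
#' @return A data frame with columns `smiles_raw`, `smiles_generic`,
#'   `selfies`, `token_length`, `source_tag`.
#' @export
make_records <- function(smiles, source_tag = "input") {
  stopifnot(is.character(smiles), length(smiles) >= 1)
  generic <- canonicalize_generic(smiles, strict = FALSE)
  selfies <- rep(NA_character_, length(smiles))
  ok <- !is.na(generic)
  if (any(ok)) selfies[ok] <- smiles_to_selfies(generic[ok], strict = FALSE)
  keep <- !is.na(selfies)
  if (!any(keep)) stop("no processable molecules in input", call. = FALSE)
  if (any(!keep)) {
    message(sum(!keep), " molecule(s) dropped as unparsable or unencodable")
  }
  out <- data.frame(smiles_raw = smiles[keep],
                    smiles_generic = generic[keep],
                    selfies = selfies[keep],
                    token_length = selfies_token_length(selfies[keep]),
                    source_tag = source_tag,
                    stringsAsFactors = FALSE)
  attr(out, "n_dropped") <- sum(!keep)
  out
}

#' Length, element and duplicate filtering
#'
#' Applies the corpus filters in order: token-length window (inclusive
#' bounds), element whitelist, deduplication on canonical generic
#' SMILES.  Counts after each stage are reported.
#'
#' @param records Data frame from [make_records()].
#' @param spec A [corpus_spec()].
#' @return A list with `records` (the survivors) and `counts`, a named
#'   vector (`input`, `after_length`, `after_elements`, `after_dedup`).
#' @export
apply_filters <- function(records, spec = corpus_spec()) {
  stopifnot(is.data.frame(records),
            all(c("smiles_generic", "selfies", "token_length") %in% names(records)),
            inherits(spec, "corpus_spec"))
  n_input <- nrow(records)

  keep_len <- records$token_length >= spec$length_min &
    records$token_length <= spec$length_max
  records <- records[keep_len, , drop = FALSE]
  n_length <- nrow(records)

  keep_elem <- vapply(records$selfies, function(s) {
    all(.selfies_elements(s) %in% spec$allowed_elements)
  }, logical(1), USE.NAMES = FALSE)
  records <- records[keep_elem, , drop = FALSE]
  n_elements <- nrow(records)

  records <- records[!duplicated(records$smiles_generic), , drop = FALSE]
  n_dedup <- nrow(records)

  if (n_dedup == 0) {
    stop("corpus filtering left no molecules (empty corpus)", call. = FALSE)
  }
  rownames(records) <- NULL
  list(records = records,
       counts = c(input = n_input, after_length = n_length,
                  after_elements = n_elements, after_dedup = n_dedup))
}

#' Train/validation split
#'
#' Random, unstratified partition: `round(validation_fraction * n)`
#' records are held out.  Reproducible for a fixed `rng_seed`.
#'
#' @param records Any records data frame (at least one row per molecule).
#' @param spec A [corpus_spec()]; `validation_fraction` and `rng_seed`
#'   are used.
#' @return List with data frames `train` and `validation`.
#' @export
train_val_split <- function(records, spec = corpus_spec()) {
  stopifnot(is.data.frame(records), inherits(spec, "corpus_spec"))
  n <- nrow(records)
  if (n < 10) stop("need at least 10 records to split", call. = FALSE)
  n_val <- round(spec$validation_fraction * n)
  idx_val <- with_seed(spec$rng_seed, sample.int(n, n_val))
  val <- records[sort(idx_val), , drop = FALSE]
  train <- records[-sort(idx_val), , drop = FALSE]
  rownames(val) <- rownames(train) <- NULL
  list(train = train, validation = val)
}

#' Read a SMILES (.smi) file
#'
#' One molecule per line; an optional second, tab-separated column is
#' taken as the molecule identifier.
#'
#' @param path File path.
#' @return Data frame with columns `smiles` and `id`.
#' @export
read_smi <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  parts <- strsplit(lines, "\t")
  data.frame(smiles = vapply(parts, `[`, character(1), 1),
             id = vapply(parts, function(p) if (length(p) > 1) p[2] else NA_character_, character(1)),
             stringsAsFactors = FALSE)
}

#' Read SMILES from a CSV column
#'
#' @param path CSV file path.
#' @param smiles_col Name of the column holding SMILES (default
#'   `"smiles"`).
#' @return Data frame with columns `smiles` and (if present) `id`.
#' @export
read_smiles_csv <- function(path, smiles_col = "smiles") {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!smiles_col %in% names(df)) {
    stop("column '", smiles_col, "' not found in ", path, call. = FALSE)
  }
  out <- data.frame(smiles = df[[smiles_col]], stringsAsFactors = FALSE)
  if ("id" %in% names(df)) out$id <- as.character(df$id)
  out
}

#' Write a prepared corpus with its stage-count report
#'
#' @param split A list with `train` and `validation` from
#'   [train_val_split()].
#' @param counts Stage counts from [apply_filters()].
#' @param csv_path,report_path Output paths (CSV corpus with a
#'   `partition` column; JSON stage-count report).
#' @return `csv_path`, invisibly.
#' @export
write_corpus <- function(split, counts, csv_path, report_path = NULL) {
  corpus <- rbind(cbind(split$train, partition = "train"),
                  cbind(split$validation, partition = "validation"))
  utils::write.csv(corpus[, c("smiles_generic", "selfies", "token_length",
                              "partition")],
                   csv_path, row.names = FALSE)
  if (!is.null(report_path)) {
    jsonlite::write_json(as.list(counts), report_path, auto_unbox = TRUE)
  }
  invisible(csv_path)
}
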