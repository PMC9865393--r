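# Batch docking orchestration: 3D embedding of candidates, pluggable
# docking backends (deterministic mock; AutoDock Vina driver), average
# binding-energy ranking, and the systematic-search combinatorics
# utility.

#' Receptor specification
#'
#' A prepared receptor structure plus its search box.  Receptor
#' preparation (PDB -> PDBQT, box choice) is deliberately upstream of
#' this tool: docking results depend strongly on the search-space size,
#' so the box is explicit user input.
#'
#' @param id Receptor identifier (e.g. a PDB code such as "7NPC").
#' @param file Path to the prepared PDBQT file (may be `NA` for the
#'   mock backend).
#' @param box_center,box_size Numeric length-3 vectors, Angstroms.
#' @return Object of class `receptor_spec`.
#' @export
receptor_spec <- function(id, file = NA_character_,
                          box_center = c(0, 0, 0), box_size = c(20, 20, 20)) {
  stopifnot(is.character(id), length(id) == 1,
            length(box_center) == 3, length(box_size) == 3,
            all(box_size > 0))
  structure(list(id = id, file = file, box_center = as.numeric(box_center),
                 box_size = as.numeric(box_size)),
            class = "receptor_spec")
}

#' 3D embedding of candidate molecules
#'
#' Generates all-atom 3D coordinates (explicit hydrogens, distance-
#' geometry embedding with a force-field relaxation) for each SMILES and
#' writes one SDF per molecule when `out_dir` is given.  Deterministic
#' for a fixed seed.  Molecules that fail to embed are skipped and
#' listed in the skip report rather than aborting the batch.
#'
#' @param smiles Character vector of valid SMILES.
#' @param ids Molecule identifiers (default `mol_1 ...`).
#' @param seed Embedding seed.
#' @param out_dir Optional output directory for `<id>.sdf` files.
#' @return List: `embedded` (data frame `id`, `smiles`, `n_atoms`,
#'   `file`), `skipped` (data frame `id`, `smiles`, `reason`) and
#'   `molblocks` (named list of SDF text for the successes).
#' @export
embed_3d <- function(smiles, ids = paste0("mol_", seq_along(smiles)),
                     seed = 7L, out_dir = NULL) {
  stopifnot(is.character(smiles), length(smiles) >= 1,
            length(ids) == length(smiles))
  resp <- chem_call("embed3d", smiles = I(smiles), seed = seed)
  ok <- vapply(resp$error, is.null, logical(1))
  molblocks <- stats::setNames(lapply(which(ok), function(i) {
    resp$result[[i]]$molblock
  }), ids[ok])
  files <- rep(NA_character_, sum(ok))
  if (!is.null(out_dir) && any(ok)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    files <- file.path(out_dir, paste0(ids[ok], ".sdf"))
    for (k in seq_along(files)) writeLines(molblocks[[k]], files[k])
  }
  list(embedded = data.frame(
         id = ids[ok], smiles = smiles[ok],
         n_atoms = vapply(which(ok), function(i) resp$result[[i]]$n_atoms,
                          numeric(1)),
         file = files, stringsAsFactors = FALSE),
       skipped = data.frame(
         id = ids[!ok], smiles = smiles[!ok],
         reason = vapply(resp$error[!ok], identity, character(1)),
         stringsAsFactors = FALSE),
       molblocks = molblocks)
}

# Deterministic pseudo-energy on [-12, -4] kcal/mol from the canonical
# SMILES x receptor id pair; stands in for a docking engine so the whole
# pipeline is runnable and testable without external binaries.
mock_binding_energy <- function(smiles, receptor_id) {
  h <- string_hash01(paste(smiles, receptor_id, sep = "|"))
  round(-12 + 8 * h, 1)
}

#' Parse an AutoDock Vina log
#'
#' Extracts the best-pose (mode 1) affinity from Vina's result table.
#'
#' @param log_lines Character vector: the program's standard output.
#' @return Affinity in kcal/mol.
#' @export
parse_vina_log <- function(log_lines) {
  rows <- grep("^\\s*\\d+\\s+-?\\d+(\\.\\d+)?\\s", log_lines, value = TRUE)
  if (length(rows) == 0) {
    stop("no pose table found in Vina output", call. = FALSE)
  }
  fields <- strsplit(trimws(rows[1]), "\\s+")[[1]]
  as.numeric(fields[2])
}

#' Dock one ligand against one receptor
#'
#' The `mock` backend needs no external software and returns a
#' deterministic pseudo-energy from the (canonical SMILES, receptor id)
#' pair.  The `vina` backend runs the AutoDock Vina executable on a
#' prepared ligand PDBQT file and parses the best-pose affinity from its
#' output.
#'
#' @param ligand For `mock`: a SMILES string.  For `vina`: path to a
#'   ligand PDBQT file.
#' @param receptor A [receptor_spec()].
#' @param backend `"mock"` (default) or `"vina"`.
#' @param ligand_id Identifier recorded in the result (default: the
#'   ligand string).
#' @param vina_path Vina executable (default `"vina"` on PATH).
#' @return A one-row data frame: `ligand_id`, `receptor_id`, `energy`.
#' @export
dock <- function(ligand, receptor, backend = c("mock", "vina"),
                 ligand_id = ligand, vina_path = "vina") {
  backend <- match.arg(backend)
  stopifnot(inherits(receptor, "receptor_spec"))
  energy <- switch(backend,
    mock = {
      smi <- canonicalize_generic(ligand)
      mock_binding_energy(smi, receptor$id)
    },
    vina = {
      if (Sys.which(vina_path) == "") {
        stop("AutoDock Vina executable not found (looked for '", vina_path,
             "'); install it or use backend = 'mock'", call. = FALSE)
      }
      if (is.na(receptor$file) || !file.exists(receptor$file)) {
        stop("receptor PDBQT file missing for ", receptor$id, call. = FALSE)
      }
      args <- c("--receptor", receptor$file, "--ligand", ligand,
                "--center_x", receptor$box_center[1],
                "--center_y", receptor$box_center[2],
                "--center_z", receptor$box_center[3],
                "--size_x", receptor$box_size[1],
                "--size_y", receptor$box_size[2],
                "--size_z", receptor$box_size[3])
      out <- suppressWarnings(system2(vina_path, args, stdout = TRUE,
                                      stderr = TRUE))
      status <- attr(out, "status")
      if (!is.null(status) && status != 0) {
        stop("Vina failed for ", ligand_id, " x ", receptor$id, ":\n",
             paste(utils::tail(out, 5), collapse = "\n"), call. = FALSE)
      }
      parse_vina_log(out)
    })
  data.frame(ligand_id = ligand_id, receptor_id = receptor$id,
             energy = energy, stringsAsFactors = FALSE)
}

#' Dock a ligand set against a receptor set
#'
#' @param ligands Data frame with columns `id` and `smiles` (mock
#'   backend) or `id` and `file` (vina backend).
#' @param receptors List of [receptor_spec()] objects.
#' @param backend Passed to [dock()].
#' @param ... Passed to [dock()].
#' @return Data frame of per-pair results (`ligand_id`, `receptor_id`,
#'   `energy`).
#' @export
dock_batch <- function(ligands, receptors, backend = "mock", ...) {
  stopifnot(is.data.frame(ligands), "id" %in% names(ligands),
            length(receptors) >= 1)
  lig_col <- if (backend == "mock") "smiles" else "file"
  stopifnot(lig_col %in% names(ligands))
  out <- list()
  for (i in seq_len(nrow(ligands))) {
    for (r in receptors) {
      out[[length(out) + 1L]] <- dock(ligands[[lig_col]][i], r,
                                      backend = backend,
                                      ligand_id = ligands$id[i], ...)
    }
  }
  do.call(rbind, out)
}

#' Average binding energy per ligand
#'
#' Arithmetic mean of the per-receptor energies for each ligand;
#' non-finite entries are excluded with a warning.
#'
#' @param results Data frame from [dock_batch()] (or any table with
#'   `ligand_id`, `receptor_id`, `energy`).
#' @return Data frame: `ligand_id`, `mean_energy` (rounded to 0.01
#'   kcal/mol), `n_receptors`.
#' @export
average_binding <- function(results) {
  stopifnot(is.data.frame(results),
            all(c("ligand_id", "energy") %in% names(results)))
  if (nrow(results) == 0) stop("empty docking result set", call. = FALSE)
  bad <- !is.finite(results$energy)
  if (any(bad)) {
    warning(sum(bad), " failed pair(s) excluded from averaging", call. = FALSE)
    results <- results[!bad, , drop = FALSE]
  }
  agg <- stats::aggregate(energy ~ ligand_id, data = results,
                          FUN = function(e) c(mean = mean(e), n = length(e)))
  data.frame(ligand_id = agg$ligand_id,
             mean_energy = round(agg$energy[, "mean"], 2),
             n_receptors = as.integer(agg$energy[, "n"]),
             stringsAsFactors = FALSE)
}

#' Rank ligands by average binding energy
#'
#' Orders ligands ascending by mean energy (most negative, i.e.
#' strongest predicted binder, first) and reports the per-receptor
#' minimum with the ligand(s) achieving it.
#'
#' @param results Data frame of per-pair results.
#' @return List: `ranking` (sorted [average_binding()] table) and
#'   `receptor_min` (per receptor: minimum energy and the ligands at
#'   the minimum).
#' @export
rank_ligands <- function(results) {
  means <- average_binding(results)
  means <- means[order(means$mean_energy), , drop = FALSE]
  rownames(means) <- NULL
  per_rec <- do.call(rbind, lapply(split(results, results$receptor_id),
                                   function(d) {
    mn <- min(d$energy)
    data.frame(receptor_id = d$receptor_id[1], min_energy = mn,
               ligands = paste(sort(unique(d$ligand_id[d$energy == mn])),
                               collapse = ","),
               stringsAsFactors = FALSE)
  }))
  rownames(per_rec) <- NULL
  list(ranking = means, receptor_min = per_rec)
}

#' Size of a systematic conformational search
#'
#' Number of conformations a brute-force search over a cubic site would
#' have to evaluate: rigid translations on a grid, rigid rotations and
#' torsion angles on an angular grid:
#' `(V^(1/3)/d)^3 * (360/a)^3 * (360/a)^t`
#' for box volume `V`, grid step `d`, angle step `a` and `t` rotatable
#' bonds.  Non-integer step counts are rounded to the nearest integer
#' with a warning.
#'
#' @param box_volume Search box volume in cubic Angstroms.
#' @param grid_step Translation step in Angstroms.
#' @param angle_step Angular step in degrees.
#' @param n_torsions Number of rotatable bonds.
#' @return Conformation count (numeric, typically astronomically large).
#' @export
systematic_search_size <- function(box_volume, grid_step, angle_step,
                                   n_torsions) {
  stopifnot(box_volume > 0, grid_step > 0, angle_step > 0, n_torsions >= 0)
  edge <- box_volume^(1 / 3)
  n_grid <- edge / grid_step
  n_ang <- 360 / angle_step
  if (abs(n_ang - round(n_ang)) > 1e-6) {
    warning("angle step does not divide 360 degrees; using ",
            round(n_ang), " steps", call. = FALSE)
  }
  if (abs(n_grid - round(n_grid)) > 1e-6) {
    warning("grid step does not divide the box edge; using ",
            round(n_grid), " steps", call. = FALSE)
  }
  n_ang <- round(n_ang)
  n_grid <- round(n_grid)
  n_grid^3 * n_ang^3 * n_ang^n_torsions
}

#' Wall-clock time of a systematic search
#'
#' @param count Conformation count (see [systematic_search_size()]).
#' @param rate Evaluations per second.
#' @return Whole years (truncated).
#' @export
enumeration_time <- function(count, rate) {
  stopifnot(count > 0, rate > 0)
  floor(count / rate / (365 * 24 * 3600))
}
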