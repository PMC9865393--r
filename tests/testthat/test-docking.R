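# Docking orchestration: embedding, backends, averaging, combinatorics.

test_that("3D embedding produces sane, reproducible all-atom geometry", {
  res1 <- embed_3d("CC", ids = "ethane", seed = 4L)
  expect_identical(nrow(res1$skipped), 0L)
  expect_identical(res1$embedded$n_atoms, 8)  # 2 C + 6 H
  # parse the molblock coordinate table: C-C bond length near 1.54 A
  lines <- strsplit(res1$molblocks[["ethane"]], "\n")[[1]]
  coords <- do.call(rbind, lapply(lines[5:6], function(l) {
    as.numeric(strsplit(trimws(l), "\\s+")[[1]][1:3])
  }))
  cc <- sqrt(sum((coords[1, ] - coords[2, ])^2))
  expect_equal(cc, 1.54, tolerance = 0.05)
  res2 <- embed_3d("CC", ids = "ethane", seed = 4L)
  expect_identical(res1$molblocks, res2$molblocks)
})

test_that("unembeddable input lands in the skip report, not an abort", {
  res <- embed_3d(c("CCO", "C1CC1"), ids = c("a", "b"))
  expect_identical(res$skipped$id, character(0))
  # force a failure via an unparsable entry
  res2 <- embed_3d(c("CCO", "((bad"), ids = c("a", "b"))
  expect_identical(res2$embedded$id, "a")
  expect_identical(res2$skipped$id, "b")
})

test_that("mock backend is deterministic with energies in [-12, -4]", {
  r <- receptor_spec("7NPC")
  d1 <- dock("CCO", r)
  d2 <- dock("OCC", r)  # same molecule, different SMILES spelling
  expect_identical(d1$energy, d2$energy)
  smis <- c("CCO", "CCN", "c1ccccc1", "CC(C)O")
  energies <- vapply(smis, function(s) dock(s, r)$energy, numeric(1))
  expect_true(all(energies >= -12 & energies <= -4))
  expect_gt(length(unique(energies)), 1)
})

test_that("vina backend parses the best-pose affinity from program output", {
  log_lines <- c(
    "Detected 4 CPUs", "Reading input ... done.",
    "mode |   affinity | dist from best mode",
    "     | (kcal/mol) | rmsd l.b.| rmsd u.b.",
    "-----+------------+----------+----------",
    "   1       -9.8      0.000      0.000",
    "   2       -9.1      1.512      2.104",
    "   3       -8.4      2.001      3.420")
  expect_identical(parse_vina_log(log_lines), -9.8)
  expect_error(parse_vina_log(c("garbled", "output")), "no pose table")
})

test_that("missing vina executable gives an actionable error", {
  r <- receptor_spec("7NPC", file = "receptor.pdbqt")
  expect_error(dock("lig.pdbqt", r, backend = "vina",
                    vina_path = "definitely-not-vina"),
               "executable not found")
})

test_that("average binding energies and ranking match the published screen", {
  energies <- read.csv(system.file("extdata", "rorc_screen_energies.csv",
                                   package = "selfgen"))
  ranked <- rank_ligands(energies)
  best <- ranked$ranking[1, ]
  worst <- ranked$ranking[nrow(ranked$ranking), ]
  expect_identical(best$ligand_id, 12L)
  expect_identical(best$mean_energy, -9.8)
  expect_identical(worst$ligand_id, 5L)
  expect_identical(worst$mean_energy, -6.7)
  # every receptor's minimum is -10.0 in this screen
  expect_true(all(ranked$receptor_min$min_energy == -10))
  # ranking is invariant to row order
  shuffled <- energies[sample(nrow(energies)), ]
  expect_identical(rank_ligands(shuffled)$ranking, ranked$ranking)
  # single-receptor mean equals the single energy
  one <- average_binding(energies[energies$receptor_id == "7NPC" &
                                    energies$ligand_id == 4, ])
  expect_identical(one$mean_energy, -7.9)
})

test_that("failed pairs are excluded from averaging with a warning", {
  res <- data.frame(ligand_id = c("a", "a"), receptor_id = c("r1", "r2"),
                    energy = c(-8, NA))
  expect_warning(avg <- average_binding(res), "excluded")
  expect_identical(avg$mean_energy, -8)
  expect_error(average_binding(res[0, ]), "empty")
})

test_that("systematic search combinatorics follow the grid formula", {
  expect_identical(systematic_search_size(1, 1, 360, 0), 1)
  # analytic value: 20^3 * 36^3 * 36^4
  expect_identical(systematic_search_size(1000, 0.5, 10, 4),
                   20^3 * 36^3 * 36^4)
  expect_warning(systematic_search_size(1000, 0.5, 7, 1), "angle step")
  # one year of work at one evaluation per second, truncated
  expect_identical(enumeration_time(365 * 24 * 3600 * 1.9, 1), 1)
})
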