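# Discriminators, fragment synthesizability score, normalisation,
# composite ranking and the cascade.

test_that("rule-of-5 boundaries pass and single breaches fail", {
  panel <- data.frame(mw = c(600, 180, 500, 400, 400),
                      logp = c(1, 1.2, 5, 5.1, 2),
                      hbd = c(1, 1, 5, 1, 6),
                      hba = c(2, 4, 10, 2, 2))
  expect_identical(ro5_pass(panel), c(FALSE, TRUE, TRUE, FALSE, FALSE))
  # classic relaxed variant tolerates one violation
  expect_identical(ro5_pass(panel, max_violations = 1L),
                   rep(TRUE, 5))
})

test_that("fragment table values follow the smoothed Bernoulli ratio", {
  ft <- fixture_fragment_table()
  tab <- ft$table
  # independent recomputation of every table entry from raw counts
  fe <- mol_fragments(ft$sets$easy, radius = tab$radius)
  fh <- mol_fragments(ft$sets$hard, radius = tab$radius)
  ne <- length(fe); nh <- length(fh); p <- tab$pseudocount
  for (frag in sample(names(tab$values), 25)) {
    n_easy <- sum(vapply(fe, function(f) frag %in% f, logical(1)))
    n_hard <- sum(vapply(fh, function(f) frag %in% f, logical(1)))
    expected <- log((n_easy + p) / (ne + 2 * p)) -
      log((n_hard + p) / (nh + 2 * p))
    expect_equal(unname(tab$values[frag]), expected)
  }
  # the hand example: 3 of 4 easy, 1 of 4 hard, p = 1 -> ln 2
  expect_equal(log((3 + 1) / (4 + 2)) - log((1 + 1) / (4 + 2)), log(2))
})

test_that("synthesizability score sums the fragment contributions", {
  frags <- mol_fragments("CCO")[[1]]
  tab <- structure(list(values = setNames(seq_along(frags) * 0.5, frags),
                        unseen = -1, pseudocount = 1, radius = 2,
                        n_easy = 1, n_hard = 1),
                   class = "fragment_table")
  expect_equal(syn_score("CCO", tab), sum(seq_along(frags) * 0.5))
  # a molecule whose fragments are all unseen scores n_frags * unseen
  n_new <- length(mol_fragments("c1ccncc1Br")[[1]])
  expect_equal(syn_score("c1ccncc1Br", tab), n_new * -1)
})

test_that("fragment table serialisation round-trips bit-exactly", {
  tab <- fixture_fragment_table()$table
  csv <- withr::local_tempfile(fileext = ".csv")
  hdr <- withr::local_tempfile(fileext = ".json")
  save_fragment_table(tab, csv, hdr)
  reloaded <- load_fragment_table(csv, hdr)
  expect_identical(reloaded$values[order(names(reloaded$values))],
                   tab$values[order(names(tab$values))])
  expect_identical(reloaded$unseen, tab$unseen)
})

test_that("the trained table separates easy from hard molecules", {
  ft <- fixture_fragment_table()
  easy_scores <- syn_score(ft$sets$easy, ft$table)
  hard_scores <- syn_score(ft$sets$hard, ft$table)
  expect_gt(mean(easy_scores), mean(hard_scores))
})

test_that("min-max normalisation maps reference extremes to 0 and 1", {
  ref <- c(0.52, 0.61, 0.74, 0.80)
  expect_equal(minmax_norm(c(0.80, 0.52), ref), c(1, 0))
  expect_equal(minmax_norm(0.9, ref), 1)   # clipped above
  expect_error(minmax_norm(c(1, 2), rep(0.5, 3)), "degenerate")
  expect_equal(minmax_norm(0.7, reference = 0.7), 0)  # single-candidate rule
})

test_that("composite score is the scaled mean of the normalised pair", {
  ts <- tiny_setup()
  tab <- fixture_fragment_table()$table
  cards <- normalize_and_rank(ts$corpus$smiles_generic[1:10], tab)
  expect_equal(cards$my_score, 100 * (cards$qed_norm + cards$syn_norm) / 2)
  expect_true(all(diff(cards$my_score) <= 0))  # sorted descending
  expect_identical(cards$passed_qed, cards$qed >= 0.5)
  expect_identical(cards$passed_syn, cards$syn_score >= 0)
  # affine rescaling of the reference preserves normalised values
  ref <- data.frame(qed = cards$qed, syn_score = cards$syn_score)
  cards2 <- normalize_and_rank(ts$corpus$smiles_generic[1:10], tab,
                               reference = ref)
  expect_equal(cards2$qed_norm, cards$qed_norm)
})

test_that("cascade counts are monotone and order-independent", {
  set.seed(42)
  cards <- data.frame(passed_qed = runif(60) > 0.4,
                      passed_ro5 = runif(60) > 0.3,
                      passed_syn = runif(60) > 0.5)
  casc <- filter_cascade(cards)
  cnt <- casc$counts
  expect_lte(cnt[["qed_and_ro5"]], min(cnt[["pass_qed"]], cnt[["pass_ro5"]]))
  expect_lte(cnt[["all"]], cnt[["qed_and_ro5"]])
  expect_identical(nrow(casc$survivors), as.integer(cnt[["all"]]))
  # permuting the predicate columns leaves the surviving set unchanged
  perm <- cards[, c("passed_syn", "passed_qed", "passed_ro5")]
  names(perm) <- c("passed_qed", "passed_ro5", "passed_syn")
  casc2 <- filter_cascade(perm)
  expect_identical(casc2$counts[["all"]], cnt[["all"]])
})
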