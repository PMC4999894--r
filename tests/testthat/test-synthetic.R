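test_that("bundles are a deterministic function of the seed, byte for byte", {
  b1 <- generate_bundle(synth_config(seed = 7, n_proteins = 60,
                                     n_candidates = 10, ortholog_pairs = 2))
  b2 <- generate_bundle(synth_config(seed = 7, n_proteins = 60,
                                     n_candidates = 10, ortholog_pairs = 2))
  d1 <- file.path(tempdir(), "bundle_a")
  d2 <- file.path(tempdir(), "bundle_b")
  write_bundle(b1, d1)
  write_bundle(b2, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", file.size(file.path(d1, f))),
                     readBin(file.path(d2, f), "raw", file.size(file.path(d2, f))),
                     info = f)
  }
  b3 <- generate_bundle(synth_config(seed = 8, n_proteins = 60,
                                     n_candidates = 10, ortholog_pairs = 2))
  expect_false(identical(b1$proteome, b3$proteome))
})

test_that("degenerate configurations behave as specified", {
  expect_error(synth_config(n_candidates = 10, n_proteins = 5),
               "exceeds")
  expect_error(synth_config(go_enrichment_fold = 0.5), "fold")
  expect_error(synth_config(regime = "neutral", disorder_shift = 0.1),
               "neutral")
  expect_error(sample_extension(0), "length")
  b <- generate_bundle(synth_config(seed = 1, n_proteins = 30,
                                    n_candidates = 0, ortholog_pairs = 0))
  expect_equal(nrow(b$candidates), 0)
  expect_length(b$proteome, 30)
  expect_equal(nchar(sample_extension(1)), 1)
})

test_that("neutral extension composition matches the background to 3 SE", {
  cfg <- synth_config(seed = 5, regime = "neutral")
  set.seed(5)
  n <- 1e6
  pooled <- strsplit(sample_extension(n, cfg), "")[[1]]
  freq <- table(factor(pooled, levels = AA)) / n
  bg <- cfg$background_freq[AA]
  se <- sqrt(bg * (1 - bg) / n)
  expect_true(all(abs(freq - bg) <= 3 * se))
  # chi-square goodness of fit against the generator's own background
  gof <- chisq.test(table(factor(pooled, levels = AA)), p = bg)
  expect_gt(gof$p.value, 0.01)
})

test_that("regime biases move the targeted residue groups as configured", {
  n <- 1e5
  cfg_f <- synth_config(seed = 6, regime = "fly_like")
  set.seed(6)
  fly <- strsplit(sample_extension(n, cfg_f), "")[[1]]
  boosted <- c("P", "Q", "R", "H", "S")
  p_obs <- mean(fly %in% boosted)
  # expected mass under the doubled weights: 2*5/ (2*5 + 15) of total
  p_exp <- sum(2 / 20 * rep(1, 5)) / (2 * 5 / 20 + 15 / 20)
  expect_lt(abs(p_obs - p_exp), 3 * sqrt(p_exp * (1 - p_exp) / n))
  cfg_y <- synth_config(seed = 6, regime = "yeast_like")
  set.seed(6)
  yeast <- strsplit(sample_extension(n, cfg_y), "")[[1]]
  expect_gt(mean(yeast %in% c("Y", "L", "I", "F", "C")), 0.25 + 0.05)
  expect_lt(mean(yeast %in% c("A", "G", "D", "E", "Q")), 0.25 - 0.05)
})

test_that("motif planting hits its Poisson rate and is self-consistent", {
  pats <- default_motif_patterns()
  set.seed(11)
  exts <- setNames(vapply(1:50, function(i)
    paste0("X", random_peptide(99)), character(1)), paste0("E", 1:50))
  none <- plant_motifs(exts, pats, 0)
  expect_identical(none$extensions, exts)
  expect_equal(nrow(none$ledger), 0)

  res <- plant_motifs(exts, pats, 10)
  # 5,000 pooled residues at 10 per 100 -> Poisson(500)
  expect_lt(abs(nrow(res$ledger) - 500), 3 * sqrt(500))
  for (r in seq_len(nrow(res$ledger))) {
    row <- res$ledger[r, ]
    h <- scan_motifs(res$extensions[[row$id]],
                     pats[pats$elm_id == row$elm_id, , drop = FALSE], row$id)
    expect_true(any(h$start == row$start & h$end == row$end),
                info = sprintf("%s %s [%d,%d)", row$id, row$elm_id,
                               row$start, row$end))
  }
  # the recoded stop is never overwritten
  expect_true(all(substr(unlist(res$extensions), 1, 1) == "X"))
  expect_true(all(res$ledger$start >= 1))
})

test_that("planted GO signal has the configured fold structure", {
  ids <- sprintf("P%03d", 1:600)
  cand <- ids[1:200]
  set.seed(21)
  null_map <- plant_go(cand, ids, n_terms = 5, fold = 1, rate = 0.1)
  rate_cand <- mean(cand %in% null_map$go_map$id[null_map$go_map$term ==
                                                   null_map$marked_term])
  expect_lt(abs(rate_cand - 0.1), 3 * sqrt(0.1 * 0.9 / 200))

  set.seed(22)
  enr_map <- plant_go(cand, ids, n_terms = 5, fold = 3, rate = 0.1)
  k <- sum(cand %in% enr_map$go_map$id[enr_map$go_map$term ==
                                         enr_map$marked_term])
  expect_lt(abs(k - 60), 3 * sqrt(200 * 0.3 * 0.7))

  one <- plant_go(cand, ids, n_terms = 1, fold = 1, rate = 0.5)
  expect_equal(length(unique(one$go_map$term)), 1)
  expect_error(plant_go(cand, ids, n_terms = 2, fold = 0.5), "fold")
})

test_that("every candidate id resolves in the proteome and extensions are well formed", {
  b <- generate_bundle(synth_config(seed = 3, n_proteins = 80,
                                    n_candidates = 20))
  expect_true(all(b$candidates$id %in% names(b$proteome)))
  expect_true(all(substr(b$candidates$extension, 1, 1) == "X"))
  n_x <- vapply(strsplit(b$candidates$extension, ""),
                function(ch) sum(ch == "X"), integer(1))
  expect_true(all(n_x == 1))
  # in-frame codon count of the nucleotide form equals extension length
  expect_true(all(nchar(b$candidates$extension_nt) ==
                    3 * nchar(b$candidates$extension)))
  # planted ledger spans exactly re-match (ground truth self-consistency)
  led <- b$ledger$planted_motifs
  expect_true(all(led$id %in% b$candidates$id))
})
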