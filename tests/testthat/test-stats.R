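test_that("structural profiles use inclusive thresholds and X-aware counting", {
  s <- paste0(strrep("A", 20), "X", strrep("S", 9))
  ann <- annotate_protein("p", s)
  tab <- export_scores(ann, "disorder")
  tab$value <- 0.5                      # all residues exactly at threshold
  ann <- import_scores(ann, tab, "disorder")
  prof <- profile_segment(ann)
  # X never counts positive but stays in the denominator
  expect_equal(prof$disordered, 29 / 30)
  expect_equal(prof$pfam, 0)
  ann10 <- excise(annotate_protein("q", random_peptide(10)), 0, 10)
  tabs <- export_scores(ann10, "disorder")
  tabs$value <- c(rep(0.9, 3), rep(0.1, 7))
  expect_equal(profile_segment(import_scores(ann10, tabs, "disorder"))$disordered,
               0.3)
})

test_that("Mann-Whitney reproduces enumeration on worked examples", {
  r <- mann_whitney(c(1, 2, 3), c(4, 5, 6))
  expect_equal(r$statistic, 0)
  expect_equal(r$p_raw, 0.1)   # 2/20 labelings as extreme
  expect_equal(mann_whitney(c(1, 2, 3), c(1, 2, 3))$p_raw, 1)
  expect_error(mann_whitney(numeric(0), 1:3), "empty")
})

test_that("the large-sample path is cross-checked by stats::wilcox.test", {
  set.seed(31)
  for (r in 1:20) {
    a <- rnorm(30); b <- rnorm(35, 0.3)
    ours <- mann_whitney(a, b)
    ref <- suppressWarnings(wilcox.test(a, b, exact = FALSE, correct = TRUE))
    expect_equal(ours$statistic, unname(ref$statistic))
    expect_lt(abs(ours$p_raw - ref$p.value), 5e-3)
  }
})

test_that("Kruskal-Wallis gates Dunn's post hoc and adjusts by comparison count", {
  same <- list(a = c(1, 1, 1), b = c(2, 2, 2) - 1, c = c(1, 1, 1))
  r0 <- kruskal_dunn(same)
  expect_equal(nrow(r0), 1)             # no post hoc on a null omnibus
  sep <- list(a = c(1, 1.1, 0.9, 1), b = c(2, 2.1, 1.9, 2),
              c = c(9, 9.1, 8.9, 9))
  r1 <- kruskal_dunn(sep)
  expect_true(r1$significant[1])
  expect_equal(nrow(r1), 4)             # omnibus + 3 pairs
  dunn <- r1[r1$test == "dunn", ]
  expect_equal(dunn$p_adjusted, pmin(1, dunn$p_raw * 3))
  expect_error(kruskal_dunn(list(1:3, 4:6)), "mann_whitney")
})

test_that("Yates goodness-of-fit matches its closed form and symmetry", {
  r <- yates_chi2_residues(50, 100, 0.5)
  expect_equal(r$statistic, 0.01, tolerance = 1e-12)
  expect_equal(yates_chi2_residues(75, 100, 0.5)$statistic, 24.01,
               tolerance = 1e-12)
  # closed-form agreement on random configurations
  set.seed(17)
  for (i in 1:50) {
    n <- sample(50:5000, 1)
    obs <- sample(0:n, 1)
    f <- runif(1, 0.05, 0.95)
    chi <- yates_chi2_residues(obs, n, f)$statistic
    direct <- (abs(obs - f * n) - 0.5)^2 / (f * n) +
      (abs((n - obs) - (1 - f) * n) - 0.5)^2 / ((1 - f) * n)
    expect_equal(chi, direct, tolerance = 1e-9)
    # swapping categories leaves the statistic unchanged
    expect_equal(chi, yates_chi2_residues(n - obs, n, 1 - f)$statistic,
                 tolerance = 1e-9)
  }
  expect_error(yates_chi2_residues(5, 10, 1), "between")
  expect_error(yates_chi2_residues(5, 0, 0.5), "n_segment")
})

test_that("Bonferroni thresholds reproduce the figure-family conventions", {
  expect_equal(bonferroni_threshold(0.05, 4), 0.0125)
  expect_equal(bonferroni_threshold(0.05, 8), 0.00625)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_error(bonferroni_threshold(0.05, 0), "m")
})

test_that("D'Agostino-Pearson separates normal from skewed samples", {
  # frozen cross-check values computed independently with scipy normaltest
  set.seed(3)
  x <- rnorm(500); y <- rexp(300)
  rx <- dagostino_pearson(x)
  expect_equal(rx$statistic, 2.577132, tolerance = 1e-6)
  expect_equal(rx$p_raw, 0.275666, tolerance = 1e-5)
  ry <- dagostino_pearson(y)
  expect_equal(ry$statistic, 117.716442, tolerance = 1e-5)
  expect_lt(ry$p_raw, 1e-20)
  # behaviour under H0 and a heavy alternative
  set.seed(41)
  p_h0 <- replicate(20, dagostino_pearson(rnorm(5000))$p_raw)
  expect_gte(mean(p_h0 > 0.01), 0.95)
  p_exp <- replicate(5, dagostino_pearson(rexp(5000))$p_raw)
  expect_true(all(p_exp < 1e-6))
  expect_error(dagostino_pearson(rep(1, 30)), "variance")
  expect_error(dagostino_pearson(rnorm(10)), "20")
})

test_that("composition log-ratios recover planted frequency changes and skip X", {
  ref <- replicate(20, random_peptide(200))
  expect_equal(unname(aa_composition_log2(ref, ref)), rep(0, 20))
  # a set in which P occurs at twice the reference frequency
  base <- rep(AA, 50)
  set_seqs <- paste(c(base, rep("P", 50)), collapse = "")
  ref_seqs <- paste(base, collapse = "")
  lr <- aa_composition_log2(set_seqs, ref_seqs)
  expect_equal(unname(lr["P"]), log2((100 / 1050) / (50 / 1000)))
  # X excluded on both sides
  expect_identical(aa_composition_log2(paste0(set_seqs, "XXXX"), ref_seqs),
                   aa_composition_log2(set_seqs, ref_seqs))
  expect_error(aa_composition_log2("AAAA", "CCCC"), "pseudocount")
})
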