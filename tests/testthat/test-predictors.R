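test_that("window entropies reproduce hand-computed values", {
  expect_equal(seg_window_entropy(strrep("A", 12), 12), 0)
  expect_equal(seg_window_entropy(paste0(strrep("A", 6), strrep("B", 6)), 12), 1)
  expect_equal(seg_window_entropy("ACDEFGHIKLMN", 12), log2(12),
               tolerance = 1e-12)
  # X occupies a position but is excluded from the composition
  expect_equal(seg_window_entropy("AAAAAAXXXXXX", 12), 0)
  expect_equal(seg_window_entropy(strrep("X", 5), 5), 0)
})

test_that("low-complexity segmentation triggers and extends as configured", {
  expect_true(all(seg_lowcomplexity(strrep("A", 12))))
  expect_true(all(seg_lowcomplexity(paste0(strrep("A", 6), strrep("B", 6)))))
  expect_false(any(seg_lowcomplexity("ACDEFGHIKLMN")))
  # a short sequence is a single window of its own length
  expect_true(all(seg_lowcomplexity("AAAA")))
  expect_error(seg_lowcomplexity(""), "empty")
})

test_that("disorder scores respond to the propensity scale", {
  expect_true(all(disorder_track(strrep("P", 40)) > 0.5))  # max propensity
  expect_true(all(disorder_track(strrep("W", 40)) < 0.5))  # min propensity
  expect_length(disorder_track("P"), 1)
  expect_error(disorder_track("AB?"), "invalid|unknown")
  # determinism
  s <- random_peptide(200)
  expect_identical(disorder_track(s), disorder_track(s))
})

test_that("secondary-structure classes follow the argmax-over-threshold rule", {
  expect_true(all(ss_track(strrep("M", 20)) == "H"))  # helix 1.45 > strand 1.05
  expect_true(all(ss_track(strrep("V", 20)) == "E"))  # strand 1.70 > helix 1.06
  expect_true(all(ss_track(strrep("G", 20)) == "C"))  # both < 1
  # tie above 1 resolves to H
  cfg <- predictor_config(ss_helix_propensity = setNames(rep(1.3, 20), AA),
                          ss_strand_propensity = setNames(rep(1.3, 20), AA))
  expect_true(all(ss_track(strrep("A", 10), cfg) == "H"))
})

test_that("binding scores are gated by disorder and driven by interaction propensity", {
  d_ord <- disorder_track(strrep("I", 30))     # ordered context
  expect_true(all(binding_track(strrep("I", 30), d_ord) == 0))
  d_r <- disorder_track(strrep("R", 30))       # disordered + interaction-prone
  expect_true(all(binding_track(strrep("R", 30), d_r) >= 0.5))
  d_p <- disorder_track(strrep("P", 30))       # disordered, minimal interaction
  expect_true(all(binding_track(strrep("P", 30), d_p) < 0.5))
  expect_error(binding_track("AAA", c(0.5, 0.5)), "length")
  expect_equal(nrow(binding_sites(binding_track(strrep("R", 30), d_r))), 1)
})

test_that("annotation unions pfam spans and validates them", {
  s <- random_peptide(80)
  ann <- annotate_protein("p", s,
                          pfam_spans = data.frame(start = c(0, 40),
                                                  end = c(50, 60)))
  expect_true(all(ann$pfam[1:60]))
  expect_false(any(ann$pfam[61:80]))
  expect_false(any(annotate_protein("p", s)$pfam))
  expect_error(annotate_protein("p", s,
                                pfam_spans = data.frame(start = 70, end = 90)),
               "outside")
})

test_that("excision returns stored full-protein values and is idempotent", {
  set.seed(4)
  s <- random_peptide(150)
  ann <- annotate_protein("p", s)
  full <- excise(ann, 0, 150)
  expect_identical(full$disorder, ann$disorder)
  v <- excise(ann, 100, 150)
  expect_identical(v$disorder, ann$disorder[101:150])
  expect_identical(v$ss_class, ann$ss_class[101:150])
  expect_identical(v$sequence, substr(s, 101, 150))
  # idempotence: excising the view's own full span changes nothing
  v2 <- excise(v, 0, 50)
  expect_identical(v2$disorder, v$disorder)
  # excised values are never re-predicted on the isolated segment
  iso <- disorder_track(substr(s, 101, 150))
  expect_false(isTRUE(all.equal(iso, v$disorder)))
  expect_error(excise(ann, 140, 160), "out of range")
})

test_that("score import replaces exactly one track and validates its shape", {
  s <- random_peptide(30)
  ann <- annotate_protein("p", s)
  tab <- export_scores(ann, "disorder")
  tab$value <- rev(tab$value)
  ann2 <- import_scores(ann, tab, "disorder")
  expect_identical(ann2$disorder, rev(ann$disorder))
  expect_identical(ann2$ss_class, ann$ss_class)
  # round trip
  expect_identical(export_scores(ann2, "disorder")$value, tab$value)
  expect_error(import_scores(ann, tab[-3, ], "disorder"), "contiguous")
  bad <- tab; bad$value[1] <- 1.5
  expect_error(import_scores(ann, bad, "disorder"), "\\[0,1\\]")
  dup <- rbind(tab, tab[1, ])
  expect_error(import_scores(ann, dup, "disorder"), "duplicate")
})

test_that("X is score-neutral: tracks equal those of a mean-propensity pseudo-residue", {
  cfg <- predictor_config()
  # build a scale in which residue A already sits at the scale mean, so a
  # sequence with X should score identically to one with A in its place
  prop <- cfg$disorder_propensity
  prop["A"] <- sum(prop[setdiff(AA, "A")]) / 19   # then A = mean(prop)
  cfgx <- predictor_config(disorder_propensity = prop)
  sx <- paste0(random_peptide(20), "X", random_peptide(20))
  sa <- sub("X", "A", sx)
  expect_equal(disorder_track(sx, cfgx), disorder_track(sa, cfgx),
               tolerance = 1e-12)
})
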