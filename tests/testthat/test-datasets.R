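toy_proteome <- function() {
  p <- c(P1 = strrep("A", 100), P2 = "ACDEFGHIKL", P3 = strrep("D", 120),
         P4 = strrep("C", 105))
  attr(p, "species") <- "toy"
  p
}

toy_candidate <- function(id = "P1", cds = strrep("A", 100),
                          ext = paste0("X", strrep("S", 19)), ...) {
  defaults <- list(extension_nt = NA, evidence = "conserved",
                   readthrough_rate = NA, reads_rep1 = NA, reads_rep2 = NA)
  extra <- utils::modifyList(defaults, list(...))
  do.call(data.frame, c(list(id = id, cds_protein = cds, extension = ext,
                             stringsAsFactors = FALSE), extra))
}

test_that("candidate validation resolves ids and rescues exact sequence matches", {
  prot <- toy_proteome()
  tab <- rbind(toy_candidate("P1"),
               toy_candidate("GHOST", cds = "ACDEFGHIKL"),
               toy_candidate("MISSING", cds = "WWWWW"))
  v <- validate_candidates(tab, prot)
  expect_equal(nrow(v$candidates), 2)
  expect_setequal(v$candidates$id, c("P1", "P2"))   # GHOST remapped to P2
  expect_equal(v$report$input, 3)
  expect_equal(v$report$exclusions$reason, "no_sequence_match")
  expect_equal(v$report$input,
               v$report$kept + nrow(v$report$exclusions))
  tab2 <- rbind(toy_candidate("NOPE", cds = NA))
  v2 <- validate_candidates(tab2, prot)
  expect_equal(v2$report$exclusions$reason, "id_not_found")
  expect_error(validate_candidates(rbind(toy_candidate("P1"),
                                         toy_candidate("P1")), prot),
               "duplicate")
})

test_that("read filter requires the threshold in both replicates, inclusively", {
  tab <- rbind(toy_candidate("P1", reads_rep1 = 5, reads_rep2 = 5,
                             evidence = "ribo_profiling"),
               toy_candidate("P2", cds = "ACDEFGHIKL",
                             reads_rep1 = 4, reads_rep2 = 100,
                             evidence = "ribo_profiling"),
               toy_candidate("P3", cds = strrep("D", 120)))
  f <- apply_read_filters(tab, 5)
  expect_setequal(f$candidates$id, c("P1", "P3"))  # conjunction; NA passes
  expect_equal(f$report$exclusions$reason, "low_reads")
  tab$reads_rep1[1] <- -1
  expect_error(apply_read_filters(tab), "negative")
})

test_that("AUG filter checks the first three in-frame extension codons", {
  mk <- function(id, nt) toy_candidate(id, ext = paste0("X", strrep("K", nchar(nt) / 3 - 1)),
                                       extension_nt = nt)
  tab <- rbind(mk("P1", "ATGAAACCC"),            # codon 1
               mk("P2", "AAAATGCCC"),            # codon 2: AAA|ATG|CCC
               mk("P3", "AAACCCGGGATG"),         # codon 4 -> kept
               mk("P4", "TGAATGCCCAAA"))         # leading stop skipped, then ATG
  f <- apply_aug_filter(tab)
  expect_setequal(f$candidates$id, "P3")
  expect_setequal(f$report$exclusions$id, c("P1", "P2", "P4"))
  expect_error(apply_aug_filter(rbind(mk("P5", "ATGA"))), "divisible")
  expect_warning(apply_aug_filter(rbind(toy_candidate("P6"))), "pass")
})

test_that("segment sets follow the span arithmetic of the design", {
  prot <- toy_proteome()
  cand <- toy_candidate("P1")   # CDS 100, extension 20
  set.seed(1)
  sets <- build_segment_sets(prot, cand)
  expect_equal(c(sets$TRC_C$start, sets$TRC_C$end), c(80, 100))
  expect_equal(c(sets$TRC_C30$start, sets$TRC_C30$end), c(70, 100))
  expect_equal(c(sets$TRC_E$start, sets$TRC_E$end), c(100, 120))
  expect_equal(nchar(sets$TRC_E$seq), 20)
  # partition: NonTRC + TRC covers the proteome
  expect_equal(nrow(sets$NonTRC) + nrow(sets$TRC), length(prot))
  # RAND_C donor within ±5% of the extended length (120 -> [114,126])
  donor_len <- nchar(prot[[sets$RAND_C$protein_id]])
  expect_lte(abs(donor_len - 120), 0.05 * 120)
  expect_equal(sets$RAND_C$end - sets$RAND_C$start, 20)
  # reproducibility of donor sampling under the same seed
  set.seed(1)
  sets2 <- build_segment_sets(prot, cand)
  expect_identical(sets$RAND_C, sets2$RAND_C)
})

test_that("an extension longer than its CDS truncates TRC_C to the whole CDS", {
  prot <- c(P1 = strrep("A", 30), P2 = strrep("C", 48), P3 = strrep("D", 70),
            P4 = strrep("E", 300))
  cand <- toy_candidate("P1", cds = strrep("A", 30),
                        ext = paste0("X", strrep("S", 39)))  # E=40 > L=30
  set.seed(2)
  sets <- build_segment_sets(prot, cand)
  expect_equal(c(sets$TRC_C$start, sets$TRC_C$end), c(0, 30))
  expect_equal(nchar(sets$TRC_C$seq), 30)
  # no donor anywhere near length 70 -> widening fails with the candidate named
  prot_bad <- c(P1 = strrep("A", 30), P4 = strrep("E", 300))
  expect_error({set.seed(2); build_segment_sets(prot_bad, cand)}, "P1")
})

test_that("the long-extension filter is inclusive at 25 and keeps partners aligned", {
  prot <- c(P1 = strrep("A", 100), P2 = strrep("C", 100), P3 = strrep("D", 100),
            P4 = strrep("E", 118), P5 = strrep("F", 121), P6 = strrep("G", 125),
            P7 = strrep("H", 131))
  cand <- rbind(toy_candidate("P1", ext = paste0("X", strrep("S", 23))),  # 24
                toy_candidate("P2", cds = strrep("C", 100),
                              ext = paste0("X", strrep("S", 24))),        # 25
                toy_candidate("P3", cds = strrep("D", 100),
                              ext = paste0("X", strrep("S", 25))))        # 26
  set.seed(3)
  sets <- filter_long(build_segment_sets(prot, cand), 25)
  expect_setequal(sets$TRC_E_L$candidate_id, c("P2", "P3"))
  expect_equal(nrow(sets$TRC_E_L), nrow(sets$TRC_C_L))
  expect_equal(nrow(sets$TRC_E_L), nrow(sets$RAND_C_L))
  expect_setequal(sets$RAND_C_L$candidate_id, sets$TRC_E_L$candidate_id)
})

test_that("biological relevance keeps conserved cases and rate >= 1.2 inclusively", {
  tab <- rbind(toy_candidate("A1", evidence = "ribo_profiling",
                             readthrough_rate = 1.2),
               toy_candidate("A2", evidence = "conserved",
                             readthrough_rate = 0.5),
               toy_candidate("A3", evidence = "ribo_profiling",
                             readthrough_rate = 0.5),
               toy_candidate("A4", evidence = "both",
                             readthrough_rate = NA))
  f <- filter_biologically_relevant(tab, 1.2)
  expect_setequal(f$candidates$id, c("A1", "A2", "A4"))
})

test_that("proteome IO round-trips and applies the length exclusion", {
  p <- c(toy_proteome(), BIG = strrep("A", 10001))
  fa <- tempfile(fileext = ".fasta")
  write_proteome(p, fa)
  back <- read_proteome(fa, species = "toy")
  expect_equal(length(back), 4)
  expect_false("BIG" %in% names(back))
  expect_equal(attr(back, "n_excluded_too_long"), 1)
  expect_identical(c(unclass(back)), c(unclass(p))[1:4])
})
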