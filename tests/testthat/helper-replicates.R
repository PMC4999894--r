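# shared machinery for the seeded replicate simulations: builds a synthetic
# bundle, assembles the TRC_E / RAND_C segment sets and returns the
# per-segment disordered fractions of both groups.

# A desk-scale proteome occasionally cannot supply a length-matched control
# for an extreme-length draw (the matching policy errors out by design).
# Such degenerate draws carry no information about the contrast under
# study, so the replicate deterministically re-derives a fresh seed.
with_replicate_retry <- function(seed, fn, attempts = 3) {
  for (k in seq_len(attempts)) {
    out <- tryCatch(fn(seed + (k - 1) * 500000L), error = function(e) e)
    if (!inherits(out, "error")) return(out)
    if (!grepl("donor|length-matched", conditionMessage(out))) stop(out)
  }
  stop(out)
}

disorder_contrast_replicate <- function(seed, n_proteins, n_candidates,
                                        regime, disorder_shift,
                                        motif_plant_rate = 0) {
  with_replicate_retry(seed, function(seed)
    .disorder_contrast_once(seed, n_proteins, n_candidates, regime,
                            disorder_shift, motif_plant_rate))
}

.disorder_contrast_once <- function(seed, n_proteins, n_candidates,
                                    regime, disorder_shift,
                                    motif_plant_rate = 0) {
  cfg <- synth_config(seed = seed, n_proteins = n_proteins,
                      n_candidates = n_candidates, regime = regime,
                      disorder_shift = disorder_shift,
                      motif_plant_rate = motif_plant_rate,
                      ortholog_pairs = 0, go_terms = 1)
  b <- generate_bundle(cfg)
  set.seed(seed + 10000L)
  sets <- build_segment_sets(b$proteome, b$candidates)
  cand_ann <- lapply(seq_len(nrow(b$candidates)), function(i)
    annotate_protein(b$candidates$id[i],
                     paste0(b$candidates$cds_protein[i],
                            b$candidates$extension[i])))
  names(cand_ann) <- b$candidates$id
  donor_ids <- unique(sets$RAND_C$protein_id)
  don_ann <- lapply(donor_ids, function(id)
    annotate_protein(id, b$proteome[[id]]))
  names(don_ann) <- donor_ids
  list(trc_e = profile_segments(sets$TRC_E, cand_ann)$disordered,
       rand_c = profile_segments(sets$RAND_C, don_ann)$disordered,
       sets = sets)
}

go_recovery_replicate <- function(seed, fold, n_proteins = 800,
                                  n_candidates = 200) {
  with_replicate_retry(seed, function(seed)
    .go_recovery_once(seed, fold, n_proteins, n_candidates))
}

.go_recovery_once <- function(seed, fold, n_proteins = 800,
                              n_candidates = 200) {
  cfg <- synth_config(seed = seed, n_proteins = n_proteins,
                      n_candidates = n_candidates,
                      go_enrichment_fold = fold,
                      ortholog_pairs = 0, motif_plant_rate = 0)
  b <- generate_bundle(cfg)
  set.seed(seed + 30000L)
  bg <- length_matched_background(b$candidates, b$proteome)
  enr <- hypergeom_enrichment(b$candidates$id, bg, b$go_map)
  enr$p_adjusted[enr$term == b$ledger$marked_go_term]
}
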