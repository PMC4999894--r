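# end-to-end orchestration: validate -> filter -> build segment sets ->
# annotate full extended proteins -> excise -> scan motifs -> classify ->
# profile -> statistics -> composition -> enrichment -> orthologs.

#' Run configuration
#'
#' Houses the global thresholds of the analysis: disorder 0.5, motif-context
#' disorder 0.4, minimum long-extension length 25, minimum readthrough rate
#' 1.2 percent, minimum reads 5, length-matching tolerance ±5 percent,
#' motif probability cutoff 1e-3, and alpha 0.05.
#'
#' @param species species tag used to select motif patterns.
#' @param seed integer seed for all stochastic steps (control sampling).
#' @param min_ext_len `_L` threshold (residues, inclusive).
#' @param min_rate `_BR` readthrough-rate threshold (percent, inclusive).
#' @param min_reads read filter threshold (inclusive, both replicates).
#' @param length_tolerance,length_tolerance_max control length matching.
#' @param p_max strict motif chance-probability cutoff.
#' @param alpha family-wise error rate before Bonferroni division.
#' @param m_segment,m_residue Bonferroni family sizes for the segment-level
#'   (one property family vs pooled references) and residue-level
#'   (4 properties x 2 references) designs.
#' @param predictor a [predictor_config()].
#' @param aligner an [alignment_params()] list.
#' @return an object of class `"run_config"`.
#' @export
run_config <- function(species = "synthetic", seed = 1,
                       min_ext_len = 25, min_rate = 1.2, min_reads = 5,
                       length_tolerance = 0.05, length_tolerance_max = 0.10,
                       p_max = 1e-3, alpha = 0.05,
                       m_segment = 4, m_residue = 8,
                       predictor = predictor_config(),
                       aligner = alignment_params()) {
  structure(list(species = species, seed = as.integer(seed),
                 min_ext_len = min_ext_len, min_rate = min_rate,
                 min_reads = min_reads,
                 length_tolerance = length_tolerance,
                 length_tolerance_max = length_tolerance_max,
                 p_max = p_max, alpha = alpha,
                 m_segment = m_segment, m_residue = m_residue,
                 predictor = predictor, aligner = aligner),
            class = "run_config")
}

# annotate the extended forms of all candidates, keyed by candidate id
.annotate_candidates <- function(candidates, config) {
  anns <- lapply(seq_len(nrow(candidates)), function(i)
    annotate_protein(candidates$id[i],
                     paste0(candidates$cds_protein[i],
                            candidates$extension[i]),
                     config = config$predictor))
  names(anns) <- candidates$id
  anns
}

# annotate arbitrary proteome entries (e.g. RAND_C donors)
.annotate_proteins <- function(ids, proteome, config) {
  anns <- lapply(ids, function(id)
    annotate_protein(id, proteome[[id]], config = config$predictor))
  names(anns) <- ids
  anns
}

#' Structural profiles for the segments of one set
#'
#' Excises each segment from its full-protein annotation and profiles it.
#'
#' @param segments one segment data.frame from [build_segment_sets()].
#' @param annotations named list of full-protein annotations covering every
#'   `protein_id` in `segments`.
#' @return data.frame of per-segment profiles.
#' @export
profile_segments <- function(segments, annotations) {
  rows <- lapply(seq_len(nrow(segments)), function(i) {
    ann <- annotations[[segments$protein_id[i]]]
    if (is.null(ann))
      stop("no annotation for ", segments$protein_id[i], call. = FALSE)
    profile_segment(excise(ann, segments$start[i], segments$end[i]))
  })
  do.call(rbind, rows)
}

# segment-level contrasts (box-plot design): per property, Kruskal-Wallis
# across TRC_E / RAND_C / TRC_C followed by Dunn's, at alpha / m_segment
.segment_stats <- function(profiles_by_set, config) {
  props <- c("disordered", "low_complexity", "secondary_structure",
             "binding_site")
  thr <- bonferroni_threshold(config$alpha, config$m_segment)
  out <- NULL
  for (pr in props) {
    groups <- lapply(profiles_by_set, function(df) df[[pr]])
    res <- kruskal_dunn(groups, alpha = config$alpha,
                        alpha_corrected = thr, property = pr)
    out <- rbind(out, res)
  }
  out
}

# residue-level contrasts (bar-chart design): per property and reference,
# Yates goodness-of-fit of pooled positive extension residues against the
# reference fraction, at alpha / m_residue
.residue_stats <- function(sets, annotations_by_set, config) {
  thr <- bonferroni_threshold(config$alpha, config$m_residue)
  positive_counts <- function(set_name, segs) {
    anns <- annotations_by_set[[set_name]]
    tot <- 0L
    pos <- c(disordered = 0, low_complexity = 0,
             secondary_structure = 0, binding_site = 0)
    for (i in seq_len(nrow(segs))) {
      v <- excise(anns[[segs$protein_id[i]]], segs$start[i], segs$end[i])
      notx <- .chars(v$sequence) != "X"
      cfg <- v$config
      tot <- tot + v$length
      pos["disordered"] <- pos["disordered"] +
        sum(v$disorder >= cfg$theta_disorder & notx)
      pos["low_complexity"] <- pos["low_complexity"] +
        sum(v$low_complexity & notx)
      pos["secondary_structure"] <- pos["secondary_structure"] +
        sum(v$ss_class %in% c("H", "E") & notx)
      pos["binding_site"] <- pos["binding_site"] +
        sum(v$binding >= cfg$theta_binding & notx)
    }
    list(total = tot, positive = pos)
  }
  cn <- positive_counts("TRC_E", sets$TRC_E)
  out <- NULL
  for (ref in c("RAND_C", "TRC_C")) {
    cr <- positive_counts(ref, sets[[ref]])
    for (pr in names(cn$positive)) {
      frac <- cr$positive[[pr]] / cr$total
      if (frac <= 0 || frac >= 1) next  # degenerate reference
      out <- rbind(out, yates_chi2_residues(
        cn$positive[[pr]], cn$total, frac, property = pr,
        groups = c("TRC_E", ref), alpha_corrected = thr))
    }
  }
  out
}

#' Run the full readthrough-extension analysis
#'
#' Executes the complete pipeline on a proteome plus candidate table (or a
#' [generate_bundle()] result): candidate validation, read/AUG/rate
#' filters, segment-set construction, full-protein annotation and segment
#' excision, motif scanning and classification, segment- and residue-level
#' statistics, amino-acid composition, GO enrichment against a
#' length-matched background, and ortholog extension comparison.
#'
#' @param bundle a `"synth_bundle"` or a list with elements `proteome`,
#'   `candidates`, `patterns`, and optionally `go_map`, `orthologs`,
#'   `ortholog_candidates`.
#' @param config a [run_config()].
#' @return an object of class `"tr_run"`.
#' @export
run_tr_analysis <- function(bundle, config = run_config()) {
  set.seed(config$seed)
  proteome <- bundle$proteome
  val <- validate_candidates(bundle$candidates, proteome)
  rd <- apply_read_filters(val$candidates, config$min_reads)
  aug <- if (any(!is.na(rd$candidates$extension_nt)))
    apply_aug_filter(rd$candidates) else
      list(candidates = rd$candidates,
           report = .filter_report(nrow(rd$candidates),
                                   rd$candidates$id,
                                   data.frame(id = character(0),
                                              reason = character(0))))
  candidates <- aug$candidates
  reports <- list(validate = val$report, reads = rd$report,
                  aug = aug$report)

  sets <- build_segment_sets(proteome, candidates,
                             tolerance = config$length_tolerance,
                             tolerance_max = config$length_tolerance_max)
  sets <- filter_long(sets, config$min_ext_len)
  br <- filter_biologically_relevant(candidates, config$min_rate)
  reports$biologically_relevant <- br$report

  cand_ann <- .annotate_candidates(candidates, config)
  donor_ann <- .annotate_proteins(unique(sets$RAND_C$protein_id),
                                  proteome, config)
  ann_by_set <- list(TRC_E = cand_ann, TRC_C = cand_ann,
                     TRC_C30 = cand_ann, RAND_C = donor_ann)

  profiles <- list()
  for (nm in c("TRC_E", "TRC_C", "TRC_C30", "RAND_C"))
    profiles[[nm]] <- profile_segments(sets[[nm]], ann_by_set[[nm]])

  patterns <- if (!is.null(bundle$patterns$taxa))
    load_patterns(bundle$patterns, config$species) else bundle$patterns

  hits <- list()
  for (i in seq_len(nrow(candidates))) {
    id <- candidates$id[i]
    L <- nchar(candidates$cds_protein[i])
    E <- nchar(candidates$extension[i])
    h <- scan_motifs(paste0(candidates$cds_protein[i],
                            candidates$extension[i]), patterns, id)
    hits[[id]] <- classify_hits(h, cand_ann[[id]], L, L + E,
                                config$predictor$theta_elm_disorder)
  }
  hit_table <- if (length(hits)) do.call(rbind, hits) else NULL
  rownames(hit_table) <- NULL

  stats_segment <- .segment_stats(
    profiles[c("TRC_E", "RAND_C", "TRC_C")], config)
  stats_residue <- .residue_stats(sets, ann_by_set, config)

  composition <- if (nrow(sets$TRC_E) && nrow(sets$NonTRC))
    aa_composition_log2(sets$TRC_E$seq, sets$NonTRC$seq, pseudocount = 0.5)
  else NULL

  enrichment <- NULL
  if (!is.null(bundle$go_map) && nrow(candidates)) {
    bg <- length_matched_background(candidates, proteome,
                                    config$length_tolerance,
                                    config$length_tolerance_max)
    enrichment <- hypergeom_enrichment(candidates$id, bg, bundle$go_map)
  }

  ortho <- NULL
  if (!is.null(bundle$orthologs) && nrow(bundle$orthologs)) {
    oc <- bundle$ortholog_candidates
    ortho <- lapply(seq_len(nrow(bundle$orthologs)), function(p) {
      ca <- oc[oc$id == bundle$orthologs$id_a[p], ]
      cb <- oc[oc$id == bundle$orthologs$id_b[p], ]
      pair <- align_pair(ca, cb, config$aligner)
      scan_cls <- function(cand) {
        ext <- cand$extension
        h <- scan_motifs(ext, patterns, cand$id)
        h
      }
      sm <- shared_motifs(pair, scan_cls(ca), scan_cls(cb),
                          p_max = config$p_max)
      list(pair = pair, shared = sm)
    })
  }

  structure(list(candidates = candidates, reports = reports,
                 segment_sets = sets, annotations = cand_ann,
                 donor_annotations = donor_ann,
                 profiles = profiles, hits = hit_table,
                 stats_segment = stats_segment,
                 stats_residue = stats_residue,
                 composition = composition,
                 enrichment = enrichment,
                 orthologs = ortho,
                 manifest = list(
                   seed = config$seed,
                   species = config$species,
                   thresholds = config[c("min_ext_len", "min_rate",
                                         "min_reads", "length_tolerance",
                                         "p_max", "alpha")],
                   n_proteome = length(proteome),
                   n_candidates = nrow(candidates),
                   extension_residues = sum(nchar(candidates$extension)),
                   timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
            class = "tr_run")
}

#' @export
print.tr_run <- function(x, ...) {
  cat(sprintf("tr_run: %d candidates over a %d-protein proteome (seed %d)\n",
              x$manifest$n_candidates, x$manifest$n_proteome,
              x$manifest$seed))
  cat(sprintf("  extension residues: %d; motif hits: %d (%d in extensions)\n",
              x$manifest$extension_residues,
              if (is.null(x$hits)) 0L else nrow(x$hits),
              if (is.null(x$hits)) 0L else sum(x$hits$in_extension)))
  invisible(x)
}

#' @export
summary.tr_run <- function(object, ...) {
  cat("Segment-level contrasts (Kruskal-Wallis + Dunn):\n")
  print(object$stats_segment, row.names = FALSE)
  cat("\nResidue-level contrasts (Yates chi-square):\n")
  print(object$stats_residue, row.names = FALSE)
  if (!is.null(object$enrichment)) {
    cat("\nTop GO enrichment rows:\n")
    print(utils::head(object$enrichment, 5), row.names = FALSE)
  }
  invisible(object)
}

#' Per-candidate summary metrics
#'
#' Emits, per candidate, the row layout used for tabulating validated
#' readthrough extensions: CDS and extension lengths, the four structural
#' percentage contents of the extension (disorder, low complexity,
#' secondary structure, binding sites; one decimal, halves away from zero,
#' denominators include the `X` residue), the count of binding sites, the
#' motif-with-disorder density per 100 residues with its
#' `(total/with-disorder/with-binding)` hit triple, and the low-probability
#' motif ids.
#'
#' @param run a [run_tr_analysis()] result.
#' @param p_max strict probability cutoff for the listed motif ids.
#' @return data.frame, one row per candidate.
#' @export
summarize_table1 <- function(run, p_max = 1e-3) {
  cands <- run$candidates
  rows <- lapply(seq_len(nrow(cands)), function(i) {
    id <- cands$id[i]
    L <- nchar(cands$cds_protein[i])
    E <- nchar(cands$extension[i])
    ann <- run$annotations[[id]]
    ext <- excise(ann, L, L + E)
    prof <- profile_segment(ext)
    nsites <- nrow(binding_sites(ext$binding, ann$config$theta_binding))
    h <- run$hits[run$hits$protein_id == id & run$hits$in_extension, ,
                  drop = FALSE]
    n_tot <- nrow(h)
    n_dis <- sum(h$overlaps_disorder)
    n_bind <- sum(h$overlaps_disorder & h$overlaps_binding)
    dens <- elm_density(n_dis, E)$rounded
    lowp <- unique(h$elm_id[h$probability < p_max])
    data.frame(id = id, cds_length = L, ext_length = E,
               disorder_pct = round_half_away(100 * prof$disordered, 1),
               low_complexity_pct = round_half_away(100 * prof$low_complexity, 1),
               secondary_structure_pct =
                 round_half_away(100 * prof$secondary_structure, 1),
               binding_site_pct = round_half_away(100 * prof$binding_site, 1),
               anchor_sites = nsites,
               elm_density = dens,
               elm_triple = sprintf("%d/%d/%d", n_tot, n_dis, n_bind),
               low_probability_elms = paste(lowp, collapse = ","),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
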