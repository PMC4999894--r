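# synthetic proteome / candidate / motif / GO / ortholog generator with
# planted, parameterized effects, so every downstream stage can be tested
# against a known ground truth without any external download.

#' Default synthetic motif pattern set
#'
#' A small set of fixed-length ELM-style patterns with exemplars that match
#' their own expression, chance-occurrence probabilities spanning the range
#' around the 1e-3 reporting cutoff, and a C-terminally anchored
#' PTS1-style pattern (never used for planting).
#'
#' @return pattern data.frame with columns `elm_id`, `pattern`,
#'   `probability`, `taxa`, `exemplar`.
#' @export
default_motif_patterns <- function() {
  data.frame(
    elm_id = c("SYN_PXXP", "SYN_DBOX", "SYN_NLS", "SYN_TRG", "SYN_SH3",
               "SYN_DEG", "SYN_PDZ", "SYN_PTS1"),
    pattern = c("P..P", "R..L..[LIVM]", "K[KR].K", "Y..[LI]",
                "[RK]..P..P", "[ST]P.[KR]", "[ST].[VIL]C", "[SAC][KR][LM]$"),
    probability = c(4.1e-3, 7.6e-4, 8.9e-4, 2.4e-3, 2.1e-4,
                    9.4e-4, 5.0e-4, 6.3e-5),
    taxa = "synthetic",
    exemplar = c("PAAP", "RAALAAL", "KKAK", "YAAL",
                 "RAAPAAP", "SPAK", "SAVC", "SKL"),
    stringsAsFactors = FALSE)
}

#' Synthetic-bundle configuration
#'
#' Parameters of the synthetic proteome and its planted effects.  Protein
#' and extension lengths are log-normal; extension composition follows the
#' regime (`fly_like` boosts the disorder-promoting residues P,Q,R,H,S;
#' `yeast_like` boosts the hydrophobics Y,L,I,F,C and depletes A,G,D,E,Q;
#' `neutral` uses the background).  `disorder_shift` is the target
#' difference in mean disordered-residue fraction between extensions and
#' length-matched control C-termini, planted by tilting the extension
#' composition toward disorder-promoting residues with an analytically
#' calibrated mixing weight.
#'
#' @param seed integer seed; the whole bundle is a deterministic function
#'   of the configuration.
#' @param n_proteins,n_candidates proteome size and number of readthrough
#'   candidates (`n_candidates <= n_proteins`).
#' @param length_log_mean,length_log_sd log-normal parameters for protein
#'   length (residues).
#' @param ext_length_log_mean,ext_length_log_sd same for extension length
#'   (the leading `X` counts toward the length).
#' @param regime `"fly_like"`, `"yeast_like"` or `"neutral"`.
#' @param composition_bias named multiplicative weights on the background
#'   residue frequencies (default: the regime's canonical bias).
#' @param background_freq named background frequencies (default uniform
#'   1/20; a measured frequency table may be supplied).
#' @param disorder_shift target disordered-fraction difference (fraction
#'   units); must be 0 under the neutral regime.
#' @param motif_plant_rate expected planted motifs per 100 extension
#'   residues.
#' @param patterns motif pattern set used for planting and bundled with the
#'   output.
#' @param go_terms number of GO terms; the first is the marked term.
#' @param go_background_rate per-term annotation probability.
#' @param go_enrichment_fold planted fold (>= 1) for the marked term among
#'   candidates.
#' @param ortholog_pairs number of synthetic ortholog pairs.
#' @param cds_identity target fractional identity of ortholog CDS regions.
#' @param read_mean,read_dispersion negative-binomial mean and size for the
#'   per-replicate extension read counts.
#' @return an object of class `"synth_config"`.
#' @export
synth_config <- function(seed = 1,
                         n_proteins = 300,
                         n_candidates = 50,
                         length_log_mean = log(400),
                         length_log_sd = 0.6,
                         ext_length_log_mean = log(30),
                         ext_length_log_sd = 0.8,
                         regime = c("neutral", "fly_like", "yeast_like"),
                         composition_bias = NULL,
                         background_freq = NULL,
                         disorder_shift = 0,
                         motif_plant_rate = 1,
                         patterns = default_motif_patterns(),
                         go_terms = 20,
                         go_background_rate = 0.1,
                         go_enrichment_fold = 3,
                         ortholog_pairs = 12,
                         cds_identity = 0.7,
                         read_mean = 50,
                         read_dispersion = 5) {
  regime <- match.arg(regime)
  if (n_candidates > n_proteins)
    stop("n_candidates exceeds n_proteins", call. = FALSE)
  if (any(c(n_proteins, n_candidates, go_terms, ortholog_pairs,
            motif_plant_rate) < 0))
    stop("counts and rates must be non-negative", call. = FALSE)
  if (go_enrichment_fold < 1)
    stop("go_enrichment_fold must be >= 1", call. = FALSE)
  if (is.null(background_freq)) {
    background_freq <- rep(1 / 20, 20)
    names(background_freq) <- AA20
  }
  background_freq <- background_freq[AA20] / sum(background_freq[AA20])
  if (is.null(composition_bias)) {
    composition_bias <- rep(1, 20)
    names(composition_bias) <- AA20
    if (regime == "fly_like") {
      composition_bias[c("P", "Q", "R", "H", "S")] <- 2
    } else if (regime == "yeast_like") {
      composition_bias[c("Y", "L", "I", "F", "C")] <- 2
      composition_bias[c("A", "G", "D", "E", "Q")] <- 0.5
    }
  }
  if (any(composition_bias[AA20] <= 0))
    stop("composition weights must be positive", call. = FALSE)
  if (regime == "neutral" &&
      (disorder_shift != 0 || any(composition_bias[AA20] != 1)))
    stop("neutral regime requires disorder_shift = 0 and identity bias",
         call. = FALSE)
  structure(list(seed = as.integer(seed),
                 n_proteins = n_proteins, n_candidates = n_candidates,
                 length_log_mean = length_log_mean,
                 length_log_sd = length_log_sd,
                 ext_length_log_mean = ext_length_log_mean,
                 ext_length_log_sd = ext_length_log_sd,
                 regime = regime,
                 composition_bias = composition_bias[AA20],
                 background_freq = background_freq,
                 disorder_shift = disorder_shift,
                 motif_plant_rate = motif_plant_rate,
                 patterns = patterns,
                 go_terms = go_terms,
                 go_background_rate = go_background_rate,
                 go_enrichment_fold = go_enrichment_fold,
                 ortholog_pairs = ortholog_pairs,
                 cds_identity = cds_identity,
                 read_mean = read_mean, read_dispersion = read_dispersion),
            class = "synth_config")
}

# regime composition before any disorder tilt
.regime_composition <- function(config) {
  w <- config$background_freq * config$composition_bias
  w / sum(w)
}

# residues used to tilt composition toward disorder
.DISORDER_TILT_SET <- c("R", "K", "Q", "S", "E", "P")

# Analytic calibration of the composition mixing weight that plants a
# target marginal disordered-fraction difference.  The disorder score of a
# residue is a logistic of its window-mean propensity, crossing 0.5 at the
# scale center, so the disordered fraction is P(window mean >= center)
# which a Gaussian window-mean approximation turns into a normal quantile
# calculation; a junction-attenuation factor accounts for the part of an
# extension residue's window that reaches into the (untilted) CDS.
.disorder_mix_weight <- function(config, pconf = predictor_config()) {
  shift <- config$disorder_shift
  if (shift <= 0) return(0)
  prop <- pconf$disorder_propensity
  W <- pconf$disorder_window
  comp0 <- .regime_composition(config)
  mu0 <- sum(comp0 * prop)
  sd0 <- sqrt(sum(comp0 * prop^2) - mu0^2)
  sigw <- sd0 / sqrt(W)
  center <- pconf$disorder_logistic_center
  p0 <- stats::pnorm((mu0 - center) / sigw)
  p1 <- min(p0 + shift, 0.99)
  delta <- sigw * (stats::qnorm(p1) - stats::qnorm(p0))
  # attenuation: average fraction of a window lying inside an extension of
  # the configured expected length (windows truncate at the C-terminus and
  # reach into the CDS on the left)
  E <- max(2, round(exp(config$ext_length_log_mean +
                          config$ext_length_log_sd^2 / 2)))
  hl <- (W - 1) %/% 2; hr <- W - 1 - hl
  t <- seq_len(E)
  wsize <- pmin(t + hr, E) - (t - hl) + 1
  inside <- pmin(t + hr, E) - pmax(t - hl, 1) + 1
  alpha <- mean(inside / wsize)
  comp_dis <- stats::setNames(rep(0, 20), AA20)
  comp_dis[.DISORDER_TILT_SET] <- 1 / length(.DISORDER_TILT_SET)
  mu_dis <- sum(comp_dis * prop)
  if (mu_dis <= mu0) stop("tilt set does not raise mean propensity")
  min(1, delta / (alpha * (mu_dis - mu0)))
}

# extension residue composition including the disorder tilt
.extension_composition <- function(config, pconf = predictor_config()) {
  comp0 <- .regime_composition(config)
  lam <- .disorder_mix_weight(config, pconf)
  if (lam == 0) return(comp0)
  comp_dis <- stats::setNames(rep(0, 20), AA20)
  comp_dis[.DISORDER_TILT_SET] <- 1 / length(.DISORDER_TILT_SET)
  (1 - lam) * comp0 + lam * comp_dis
}

#' Sample an extension peptide
#'
#' Draws `length` residues from the configured regime composition
#' (including any planted disorder tilt).  The leading stop-codon `X` of a
#' full extension is NOT added here; [generate_bundle()] prepends it.
#'
#' @param length peptide length (>= 1).
#' @param config a [synth_config()].
#' @return a peptide string.
#' @export
sample_extension <- function(length, config = synth_config()) {
  if (length < 1) stop("length must be >= 1", call. = FALSE)
  comp <- .extension_composition(config)
  paste(sample(AA20, length, replace = TRUE, prob = comp), collapse = "")
}

.sample_background <- function(n, config) {
  paste(sample(AA20, n, replace = TRUE, prob = config$background_freq),
        collapse = "")
}

#' Plant motif exemplars into extensions
#'
#' Substitutes literal exemplar strings at uniformly chosen, non-overlapping
#' positions, at an expected Poisson rate of `rate` plants per 100 residues
#' per extension.  Only unanchored patterns with an exemplar are used; the
#' position of the recoded stop (`X`, position 0) is never overwritten.  An
#' exemplar that cannot be placed (extension too short or saturated) is
#' skipped and logged, never truncated.
#'
#' @param extensions named character vector of extension peptides (leading
#'   `X` included).
#' @param patterns pattern data.frame with `elm_id`, `pattern`, `exemplar`.
#' @param rate expected plants per 100 residues.
#' @return list with `extensions` (modified) and `ledger` (data.frame
#'   `id`, `elm_id`, `start`, `end` on 0-based extension-local coordinates)
#'   and `skipped` (count of unplaceable plants).
#' @export
plant_motifs <- function(extensions, patterns, rate) {
  usable <- patterns[!grepl("[$^]", patterns$pattern) &
                       !is.na(patterns$exemplar) &
                       nzchar(patterns$exemplar), , drop = FALSE]
  ledger <- list()
  skipped <- 0L
  if (rate > 0 && nrow(usable)) {
    for (nm in names(extensions)) {
      ext <- extensions[[nm]]
      len <- nchar(ext)
      k <- stats::rpois(1, rate * len / 100)
      if (k == 0) next
      occupied <- rep(FALSE, len)
      occupied[1] <- TRUE   # the X at position 0 stays
      for (q in seq_len(k)) {
        p <- usable[sample.int(nrow(usable), 1), ]
        le <- nchar(p$exemplar)
        if (le > len - 1L) { skipped <- skipped + 1L; next }
        # starts (1-based) whose le-wide footprint is free
        free <- !occupied
        ok <- which(vapply(seq_len(len - le + 1L),
                           function(s) all(free[s:(s + le - 1L)]),
                           logical(1)))
        if (!length(ok)) { skipped <- skipped + 1L; next }
        s <- ok[sample.int(length(ok), 1)]
        substr(ext, s, s + le - 1L) <- p$exemplar
        occupied[s:(s + le - 1L)] <- TRUE
        ledger[[length(ledger) + 1L]] <-
          data.frame(id = nm, elm_id = p$elm_id,
                     start = s - 1L, end = s - 1L + le,
                     stringsAsFactors = FALSE)
      }
      extensions[[nm]] <- ext
    }
  }
  ledger <- if (length(ledger)) do.call(rbind, ledger) else
    data.frame(id = character(0), elm_id = character(0),
               start = integer(0), end = integer(0), stringsAsFactors = FALSE)
  list(extensions = extensions, ledger = ledger, skipped = skipped)
}

#' Plant a GO enrichment signal
#'
#' Assigns `n_terms` flat GO terms: the first (marked) term annotates
#' candidates with probability `min(1, fold * rate)` and non-candidates
#' with probability `rate`; all remaining terms annotate every protein
#' uniformly with probability `rate`.
#'
#' @param candidate_ids candidate protein ids.
#' @param all_ids all proteome ids.
#' @param n_terms number of terms (>= 1).
#' @param fold planted fold (>= 1) for the marked term.
#' @param rate background annotation probability per term.
#' @return list with `go_map` (data.frame `id`, `term`) and `marked_term`.
#' @export
plant_go <- function(candidate_ids, all_ids, n_terms, fold, rate = 0.1) {
  if (fold < 1) stop("fold must be >= 1", call. = FALSE)
  if (n_terms < 1) stop("n_terms must be >= 1", call. = FALSE)
  terms <- sprintf("GO:SYN%04d", seq_len(n_terms))
  rows <- list()
  is_cand <- all_ids %in% candidate_ids
  p_marked <- ifelse(is_cand, pmin(1, fold * rate), rate)
  hit <- stats::runif(length(all_ids)) < p_marked
  if (any(hit))
    rows[[1]] <- data.frame(id = all_ids[hit], term = terms[1],
                            stringsAsFactors = FALSE)
  for (t in seq_len(n_terms)[-1]) {
    hit <- stats::runif(length(all_ids)) < rate
    if (any(hit))
      rows[[length(rows) + 1L]] <- data.frame(id = all_ids[hit],
                                              term = terms[t],
                                              stringsAsFactors = FALSE)
  }
  go_map <- if (length(rows)) do.call(rbind, rows) else
    data.frame(id = character(0), term = character(0), stringsAsFactors = FALSE)
  list(go_map = go_map, marked_term = terms[1])
}

# reverse-translate a peptide with uniformly chosen synonymous codons;
# X becomes a uniformly chosen stop codon
.reverse_translate <- function(peptide) {
  gc <- Biostrings::GENETIC_CODE
  by_aa <- split(names(gc), unname(gc))
  ch <- .chars(peptide)
  cods <- vapply(ch, function(a) {
    pool <- if (a == "X") by_aa[["*"]] else by_aa[[a]]
    pool[sample.int(length(pool), 1)]
  }, character(1))
  paste(cods, collapse = "")
}

#' Generate a complete synthetic bundle
#'
#' Deterministic in the configuration seed.  Produces a proteome (candidate
#' entries are the unextended CDS forms), a candidate table with extension
#' peptides (leading `X`), reverse-translated extension nucleotides,
#' evidence classes, log-uniform readthrough rates on \[0.1, 10\] percent
#' and negative-binomial replicate read counts, planted motif instances, a
#' planted GO map, synthetic ortholog pairs (shared ancestor CDS mutated to
#' the target identity, independent extensions), and a ground-truth ledger.
#'
#' Candidate genes are drawn from proteins in the central 80 percent of the
#' length distribution so that length-matched control sampling is always
#' feasible at desk scale.
#'
#' @param config a [synth_config()].
#' @return an object of class `"synth_bundle"`: list with `proteome`,
#'   `candidates`, `patterns`, `go_map`, `orthologs`,
#'   `ortholog_candidates`, `ledger`, `config`.
#' @export
generate_bundle <- function(config = synth_config()) {
  stopifnot(inherits(config, "synth_config"))
  set.seed(config$seed)
  n <- config$n_proteins
  lens <- pmin(pmax(round(stats::rlnorm(n, config$length_log_mean,
                                        config$length_log_sd)), 30), 10000)
  ids <- sprintf("SYNP%04d", seq_len(n))
  proteome <- vapply(lens, .sample_background, character(1), config = config)
  names(proteome) <- ids
  attr(proteome, "species") <- "synthetic"

  # candidates from the central 80% of the length distribution
  qs <- stats::quantile(lens, c(0.1, 0.9), type = 1)
  eligible <- which(lens >= qs[1] & lens <= qs[2])
  if (length(eligible) < config$n_candidates)
    eligible <- order(abs(lens - stats::median(lens)))[
      seq_len(config$n_candidates)]
  cand_idx <- sort(sample(eligible, config$n_candidates))
  cand_ids <- ids[cand_idx]

  ncand <- config$n_candidates
  ext_len <- if (ncand) pmin(pmax(round(stats::rlnorm(
    ncand, config$ext_length_log_mean, config$ext_length_log_sd)), 2), 2000)
    else integer(0)
  exts <- stats::setNames(vapply(ext_len, function(E)
    paste0("X", sample_extension(E - 1L, config)), character(1)), cand_ids)

  planted <- plant_motifs(exts, config$patterns, config$motif_plant_rate)
  exts <- planted$extensions

  evid <- if (ncand) sample(c("conserved", "ribo_profiling", "both"), ncand,
                            replace = TRUE, prob = c(0.3, 0.6, 0.1))
    else character(0)
  prof <- evid %in% c("ribo_profiling", "both")
  rate <- rep(NA_real_, ncand)
  rate[prof] <- exp(stats::runif(sum(prof), log(0.1), log(10)))
  r1 <- r2 <- rep(NA_real_, ncand)
  r1[prof] <- stats::rnbinom(sum(prof), mu = config$read_mean,
                             size = config$read_dispersion)
  r2[prof] <- stats::rnbinom(sum(prof), mu = config$read_mean,
                             size = config$read_dispersion)
  ext_nt <- vapply(exts, .reverse_translate, character(1))

  candidates <- data.frame(id = cand_ids,
                           cds_protein = unname(proteome[cand_idx]),
                           extension = unname(exts),
                           extension_nt = unname(ext_nt),
                           evidence = evid,
                           readthrough_rate = rate,
                           reads_rep1 = r1, reads_rep2 = r2,
                           stringsAsFactors = FALSE)

  go <- plant_go(cand_ids, ids, config$go_terms,
                 config$go_enrichment_fold, config$go_background_rate)

  # ortholog pairs: shared ancestor CDS mutated to the target identity by
  # substitutions only; extensions drawn independently
  orth <- data.frame(id_a = character(0), id_b = character(0),
                     stringsAsFactors = FALSE)
  orth_cand <- candidates[0, c("id", "cds_protein", "extension")]
  for (p in seq_len(config$ortholog_pairs)) {
    L <- pmin(pmax(round(stats::rlnorm(1, config$length_log_mean,
                                       config$length_log_sd)), 30), 10000)
    anc <- .chars(.sample_background(L, config))
    nmut <- round((1 - config$cds_identity) * L)
    bch <- anc
    if (nmut > 0) {
      pos <- sample.int(L, nmut)
      bch[pos] <- vapply(anc[pos], function(a)
        sample(setdiff(AA20, a), 1), character(1))
    }
    ea <- paste0("X", sample_extension(max(1L, round(stats::rlnorm(
      1, config$ext_length_log_mean, config$ext_length_log_sd))), config))
    eb <- paste0("X", sample_extension(max(1L, round(stats::rlnorm(
      1, config$ext_length_log_mean, config$ext_length_log_sd))), config))
    ida <- sprintf("ORTHA%03d", p); idb <- sprintf("ORTHB%03d", p)
    orth <- rbind(orth, data.frame(id_a = ida, id_b = idb,
                                   stringsAsFactors = FALSE))
    orth_cand <- rbind(orth_cand,
                       data.frame(id = c(ida, idb),
                                  cds_protein = c(paste(anc, collapse = ""),
                                                  paste(bch, collapse = "")),
                                  extension = c(ea, eb),
                                  stringsAsFactors = FALSE))
  }

  ledger <- list(planted_motifs = planted$ledger,
                 skipped_plants = planted$skipped,
                 marked_go_term = go$marked_term,
                 background_freq = config$background_freq,
                 extension_composition = .extension_composition(config),
                 read_model = sprintf(
                   "negative binomial (mu=%g, size=%g); rate log-uniform [0.1, 10] %%",
                   config$read_mean, config$read_dispersion))

  structure(list(proteome = proteome, candidates = candidates,
                 patterns = config$patterns, go_map = go$go_map,
                 orthologs = orth, ortholog_candidates = orth_cand,
                 ledger = ledger, config = config),
            class = "synth_bundle")
}

#' @export
print.synth_bundle <- function(x, ...) {
  cat(sprintf("synth_bundle: %d proteins, %d candidates (%s regime, seed %d)\n",
              length(x$proteome), nrow(x$candidates), x$config$regime,
              x$config$seed))
  cat(sprintf("  planted motifs: %d; marked GO term: %s; ortholog pairs: %d\n",
              nrow(x$ledger$planted_motifs), x$ledger$marked_go_term,
              nrow(x$orthologs)))
  invisible(x)
}

#' Write a synthetic bundle to disk
#'
#' Proteome as FASTA; candidate table, motif set, GO map, ortholog list and
#' ground-truth motif ledger as headered TSV; the configuration as a
#' key=value text file.  Spans in the ledger are 0-based half-open.
#'
#' @param bundle a [generate_bundle()] result.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_bundle <- function(bundle, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_proteome(bundle$proteome, file.path(dir, "proteome.fasta"))
  .write_tsv(bundle$candidates, file.path(dir, "candidates.tsv"))
  .write_tsv(bundle$patterns, file.path(dir, "patterns.tsv"))
  .write_tsv(bundle$go_map, file.path(dir, "go_map.tsv"))
  .write_tsv(bundle$orthologs, file.path(dir, "orthologs.tsv"))
  .write_tsv(bundle$ortholog_candidates,
             file.path(dir, "ortholog_candidates.tsv"))
  .write_tsv(bundle$ledger$planted_motifs,
             file.path(dir, "planted_motifs.tsv"))
  cfg <- bundle$config
  scalars <- vapply(cfg, function(v) is.atomic(v) && length(v) == 1,
                    logical(1))
  writeLines(c("# synth_config (scalar fields)",
               sprintf("%s=%s", names(cfg)[scalars],
                       vapply(cfg[scalars], as.character, character(1)))),
             file.path(dir, "config.txt"))
  invisible(dir)
}
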