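# GO term enrichment against a length-matched sampled background.  Long
# proteins are over-represented among readthrough candidates, so testing
# against the whole proteome confounds term enrichment with protein length;
# instead one non-candidate of similar length is sampled per candidate and
# the test universe is study + sampled background.

#' Sample a length-matched background set
#'
#' For each candidate, one non-candidate protein whose (unextended) length
#' lies within ±`tolerance` of the candidate's CDS length is sampled without
#' replacement.  When no donor qualifies, the tolerance widens in
#' 1-percentage-point steps up to `tolerance_max`; exhaustion beyond that is
#' an error naming the candidate.
#'
#' @param candidates candidate data.frame with `id` and `cds_protein`.
#' @param proteome named character vector.
#' @param tolerance,tolerance_max length tolerances (fractions).
#' @return character vector of background protein ids,
#'   `length(candidates$id)` long.
#' @export
length_matched_background <- function(candidates, proteome,
                                      tolerance = 0.05,
                                      tolerance_max = 0.10) {
  non_ids <- setdiff(names(proteome), candidates$id)
  donor_lens <- nchar(unclass(proteome)[non_ids])
  used <- logical(length(non_ids))
  out <- character(nrow(candidates))
  for (i in seq_len(nrow(candidates))) {
    target <- nchar(candidates$cds_protein[i])
    j <- .pick_donor(target, donor_lens, used, tolerance, tolerance_max,
                     function(n) sample.int(n, 1L))
    if (is.na(j))
      stop(sprintf("no length-matched background protein within ±%d%% for %s",
                   round(100 * tolerance_max), candidates$id[i]),
           call. = FALSE)
    used[j] <- TRUE
    out[i] <- non_ids[j]
  }
  out
}

#' Read a GO annotation map
#'
#' TSV with columns `id` (protein) and `term`, one pair per row.
#'
#' @param path TSV file.
#' @return data.frame with columns `id`, `term`.
#' @export
read_go_map <- function(path) {
  df <- .read_tsv(path)
  if (!all(c("id", "term") %in% names(df)))
    stop("GO map needs columns id and term", call. = FALSE)
  df
}

#' Hypergeometric GO term enrichment
#'
#' For each term annotating the universe (study plus background), computes
#' the upper-tail hypergeometric probability of observing at least the
#' study's annotated count when drawing the study from the universe, the
#' enrichment fold `(k/n) / (K/N)` (study rate over universe rate), and
#' Benjamini-Hochberg adjusted p-values across terms.
#'
#' @param study_ids study protein ids.
#' @param background_ids sampled background ids (disjoint from the study).
#' @param go_map data.frame with columns `id`, `term`.
#' @return data.frame, one row per term, sorted by `p_adjusted`: `term`,
#'   `k` (study annotated), `n` (study size), `K` (universe annotated),
#'   `N` (universe size), `fold`, `p_raw`, `p_adjusted`.
#' @export
hypergeom_enrichment <- function(study_ids, background_ids, go_map) {
  if (!length(study_ids) || !length(background_ids))
    stop("empty study or background", call. = FALSE)
  universe <- unique(c(study_ids, background_ids))
  N <- length(universe)
  n <- length(unique(study_ids))
  gm <- go_map[go_map$id %in% universe, , drop = FALSE]
  terms <- unique(gm$term)
  rows <- lapply(terms, function(tm) {
    ann <- unique(gm$id[gm$term == tm])
    K <- length(ann)
    k <- length(intersect(ann, study_ids))
    p <- if (k == 0) 1 else
      stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    fold <- if (K == 0) 0 else (k / n) / (K / N)
    data.frame(term = tm, k = k, n = n, K = K, N = N, fold = fold,
               p_raw = p, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    return(data.frame(term = character(0), k = integer(0), n = integer(0),
                      K = integer(0), N = integer(0), fold = numeric(0),
                      p_raw = numeric(0), p_adjusted = numeric(0)))
  out$p_adjusted <- stats::p.adjust(out$p_raw, method = "BH")
  out[order(out$p_adjusted, out$p_raw), , drop = FALSE]
}
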