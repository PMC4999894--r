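# per-residue structural tracks.  All scorers run on the FULL extended
# protein; segment values are excised afterwards, never re-predicted on the
# isolated segment, so that window context at segment borders is the real
# protein context.

# map residues to propensities; X gets the scale mean
.propensity_values <- function(chars, scale, what) {
  v <- unname(scale[chars])
  isx <- chars == "X"
  if (any(isx)) v[isx] <- mean(scale)
  if (anyNA(v))
    stop(sprintf("unknown residue(s) in %s: %s", what,
                 paste(unique(chars[is.na(v) & !isx]), collapse = ", ")),
         call. = FALSE)
  v
}

#' SEG-style low-complexity segmentation
#'
#' Computes the Shannon entropy K2 (bits) of the residue composition of each
#' sliding window of width `seg_window` and marks residues that fall in
#' low-complexity regions.  Windows whose entropy is at or below the trigger
#' threshold seed a region; the region extends across contiguous windows at
#' or below the extension threshold.  `X` residues occupy positions but are
#' excluded from the composition vector (the window's effective size is the
#' count of non-X residues), so the unknown stop-codon residue cannot
#' artificially inflate window complexity.  Sequences shorter than the
#' window are evaluated as a single window of their own length.
#'
#' This is a two-threshold trigger/extend dialect of the classic algorithm,
#' without the downstream minimal-probability subsequence refinement; it is
#' used as a source of residue fractions only.
#'
#' @param seq protein sequence (single string; any letters, `X` special).
#' @param config a [predictor_config()].
#' @return logical vector, one flag per residue.
#' @export
seg_lowcomplexity <- function(seq, config = predictor_config()) {
  if (!nzchar(seq)) stop("empty sequence", call. = FALSE)
  ch <- .chars(seq)
  n <- length(ch)
  W <- min(config$seg_window, n)
  k2 <- seg_window_entropy(seq, W)
  nw <- length(k2)
  trig <- k2 <= config$seg_trigger
  ext <- k2 <= config$seg_extend
  flag <- rep(FALSE, n)
  if (any(trig)) {
    runs <- .runs_true(ext)
    for (r in seq_len(nrow(runs))) {
      idx <- (runs[r, "start"] + 1L):runs[r, "end"]   # window indices, 1-based
      if (any(trig[idx]))
        flag[runs[r, "start"] + seq_len(runs[r, "end"] - runs[r, "start"] + W - 1L)] <- TRUE
    }
    flag <- flag[seq_len(n)]
  }
  flag
}

#' Window composition entropies
#'
#' Entropy K2 in bits of each `w`-wide window's residue composition
#' (`X` excluded from the composition).  Exposed separately so the
#' segmentation can be checked against direct entropy computation.
#'
#' @param seq protein sequence.
#' @param w window width; windows slide by one residue.
#' @return numeric vector of length `max(1, nchar(seq) - w + 1)`.
#' @export
seg_window_entropy <- function(seq, w) {
  ch <- .chars(seq)
  n <- length(ch)
  w <- min(w, n)
  ch[ch == "X"] <- NA          # X occupies a position but has no symbol
  alph <- unique(ch[!is.na(ch)])
  K <- length(alph)
  nw <- max(1L, n - w + 1L)
  if (K == 0L) return(rep(0, nw))
  ind <- matrix(0L, n, K)
  idx <- match(ch, alph)
  ok <- !is.na(idx)
  ind[cbind(which(ok), idx[ok])] <- 1L
  cs <- rbind(0L, apply(ind, 2, cumsum))
  counts <- cs[(w + 1L):(w + nw), , drop = FALSE] -
    cs[1:nw, , drop = FALSE]
  tot <- rowSums(counts)
  p <- counts / ifelse(tot > 0, tot, 1)
  h <- -rowSums(ifelse(p > 0, p * log2(p), 0))
  h[tot == 0] <- 0
  h
}

#' Intrinsic-disorder score track
#'
#' Windowed mean of a per-residue disorder propensity, mapped through a
#' logistic to \[0,1\]: `score_i = logistic(gain * (mean_i - center))`.
#' Terminal windows are truncated.  Deterministic; `X` is assigned the mean
#' propensity of the scale.
#'
#' @inheritParams seg_lowcomplexity
#' @return numeric vector of per-residue scores in \[0,1\].
#' @export
disorder_track <- function(seq, config = predictor_config()) {
  if (!nzchar(seq)) stop("empty sequence", call. = FALSE)
  ch <- .chars(seq)
  v <- .propensity_values(ch, config$disorder_propensity, "disorder_track")
  m <- .window_mean(v, config$disorder_window)
  stats::plogis(config$disorder_logistic_gain *
                  (m - config$disorder_logistic_center))
}

#' Secondary-structure class track
#'
#' Windowed mean helix and strand propensities per residue; the class is the
#' argmax of the two means if that mean exceeds 1.0, otherwise coil.  Ties
#' at equal means above 1.0 are assigned helix.
#'
#' @inheritParams seg_lowcomplexity
#' @return character vector over `{"H","E","C"}`.
#' @export
ss_track <- function(seq, config = predictor_config()) {
  if (!nzchar(seq)) stop("empty sequence", call. = FALSE)
  ch <- .chars(seq)
  h <- .window_mean(.propensity_values(ch, config$ss_helix_propensity, "ss_track"),
                    config$ss_window)
  e <- .window_mean(.propensity_values(ch, config$ss_strand_propensity, "ss_track"),
                    config$ss_window)
  cls <- rep("C", length(ch))
  cls[h > 1 & h >= e] <- "H"
  cls[e > 1 & e > h] <- "E"
  cls
}

#' Disordered-binding-site score track
#'
#' ANCHOR-style stand-in: the windowed mean interaction propensity is mapped
#' through a logistic and gated by the disorder track, so only residues in a
#' (loosely) disordered context — disorder score at or above
#' `theta_elm_disorder` — can score as binding-capable.  A binding site is a
#' maximal run of residues with binding score at or above `theta_binding`.
#'
#' @param seq protein sequence.
#' @param disorder per-residue disorder score track aligned with `seq`.
#' @param config a [predictor_config()].
#' @return numeric vector of per-residue binding scores in \[0,1\].
#' @export
binding_track <- function(seq, disorder, config = predictor_config()) {
  if (!nzchar(seq)) stop("empty sequence", call. = FALSE)
  ch <- .chars(seq)
  if (length(disorder) != length(ch))
    stop("disorder track length does not match sequence", call. = FALSE)
  v <- .propensity_values(ch, config$binding_propensity, "binding_track")
  m <- .window_mean(v, config$binding_window)
  gate <- as.numeric(disorder >= config$theta_elm_disorder)
  gate * stats::plogis(config$binding_logistic_gain *
                         (m - config$binding_logistic_center))
}

#' Binding-site spans of a binding score track
#'
#' @param binding numeric binding score track.
#' @param theta site threshold (inclusive).
#' @return integer matrix with columns `start`, `end` (0-based, half-open),
#'   one row per maximal run at or above `theta`.
#' @export
binding_sites <- function(binding, theta = 0.5) {
  .runs_true(binding >= theta)
}

#' Annotate a full-length (extended) protein
#'
#' Runs all per-residue scorers exactly once on the complete sequence
#' (CDS + recoded stop `X` + extension where applicable) and attaches the
#' Pfam occupancy track from annotation spans.  All Pfam entity types are
#' accepted; overlapping spans are unioned.
#'
#' @param id protein identifier.
#' @param seq full protein sequence.
#' @param pfam_spans optional matrix/data.frame with columns `start`,`end`
#'   (0-based half-open spans on `seq`) of Pfam entities.
#' @param config a [predictor_config()].
#' @return an object of class `"residue_annotation"`: a list with elements
#'   `id`, `length`, `disorder`, `low_complexity`, `ss_class`, `binding`,
#'   `pfam`, plus the `config` used.
#' @export
annotate_protein <- function(id, seq, pfam_spans = NULL,
                             config = predictor_config()) {
  .check_residues(seq, allow_x = TRUE, what = id)
  n <- nchar(seq)
  dis <- disorder_track(seq, config)
  ann <- list(id = id,
              length = n,
              disorder = dis,
              low_complexity = seg_lowcomplexity(seq, config),
              ss_class = ss_track(seq, config),
              binding = binding_track(seq, dis, config),
              pfam = rep(FALSE, n),
              sequence = seq,
              config = config)
  if (!is.null(pfam_spans) && nrow(pfam_spans) > 0) {
    for (r in seq_len(nrow(pfam_spans))) {
      s <- pfam_spans[r, "start"]; e <- pfam_spans[r, "end"]
      if (s < 0 || e > n || s >= e)
        stop(sprintf("pfam span [%d,%d) outside protein %s (length %d)",
                     s, e, id, n), call. = FALSE)
      ann$pfam[(s + 1L):e] <- TRUE
    }
  }
  structure(ann, class = "residue_annotation")
}

#' @export
print.residue_annotation <- function(x, ...) {
  cat(sprintf("residue_annotation: %s (%d residues)\n", x$id, x$length))
  cat(sprintf("  disordered (>=0.5): %.1f%%  low-complexity: %.1f%%  H/E: %.1f%%  binding (>=%.2g): %.1f%%  pfam: %.1f%%\n",
              100 * mean(x$disorder >= x$config$theta_disorder),
              100 * mean(x$low_complexity),
              100 * mean(x$ss_class %in% c("H", "E")),
              x$config$theta_binding,
              100 * mean(x$binding >= x$config$theta_binding),
              100 * mean(x$pfam)))
  invisible(x)
}

#' Excise a segment view from a full-protein annotation
#'
#' Returns the stored per-residue values over the span without any
#' recomputation (idempotent); this is the predict-then-excise contract that
#' keeps segment scores identical to their full-protein values.
#'
#' @param annotation a [annotate_protein()] result.
#' @param start,end 0-based half-open span on the annotated protein.
#' @return a `"residue_annotation"` covering the span, carrying `parent_span`.
#' @export
excise <- function(annotation, start, end) {
  stopifnot(inherits(annotation, "residue_annotation"))
  if (start < 0 || end > annotation$length || start >= end)
    stop(sprintf("span [%d,%d) out of range for %s (length %d)",
                 start, end, annotation$id, annotation$length), call. = FALSE)
  idx <- (start + 1L):end
  out <- annotation
  out$length <- length(idx)
  out$disorder <- annotation$disorder[idx]
  out$low_complexity <- annotation$low_complexity[idx]
  out$ss_class <- annotation$ss_class[idx]
  out$binding <- annotation$binding[idx]
  out$pfam <- annotation$pfam[idx]
  out$sequence <- substr(annotation$sequence, start + 1L, end)
  out$parent_span <- c(start = start, end = end)
  out
}

#' Overlay a precomputed per-residue score table
#'
#' Replaces one track of an annotation with externally computed values
#' (e.g. genuine IUPred/ANCHOR/PSIPRED/SEG output exported as TSV), leaving
#' the other tracks untouched.
#'
#' @param annotation a `"residue_annotation"`.
#' @param table data.frame or TSV path with columns `id`, `pos` (0-based,
#'   contiguous over the whole protein) and `value`.
#' @param track one of `"disorder"`, `"binding"` (numeric in \[0,1\]),
#'   `"low_complexity"`, `"pfam"` (0/1), `"ss_class"` (H/E/C).
#' @return the annotation with the track replaced.
#' @export
import_scores <- function(annotation, table, track) {
  stopifnot(inherits(annotation, "residue_annotation"))
  track <- match.arg(track, c("disorder", "binding", "low_complexity",
                              "pfam", "ss_class"))
  if (is.character(table)) table <- .read_tsv(table)
  tab <- table[table$id == annotation$id, , drop = FALSE]
  tab <- tab[order(tab$pos), , drop = FALSE]
  if (anyDuplicated(tab$pos))
    stop("duplicate positions in imported score table", call. = FALSE)
  if (nrow(tab) != annotation$length ||
      !identical(as.integer(tab$pos), seq_len(annotation$length) - 1L))
    stop(sprintf("imported positions for %s are not contiguous 0..%d",
                 annotation$id, annotation$length - 1L), call. = FALSE)
  val <- tab$value
  if (track %in% c("disorder", "binding")) {
    val <- as.numeric(val)
    if (any(val < 0 | val > 1))
      stop("imported score outside [0,1]", call. = FALSE)
  } else if (track %in% c("low_complexity", "pfam")) {
    val <- as.logical(as.integer(val))
  } else {
    val <- as.character(val)
    if (!all(val %in% c("H", "E", "C")))
      stop("imported ss_class values must be H, E or C", call. = FALSE)
  }
  annotation[[track]] <- val
  annotation
}

#' Export one track of an annotation as a per-residue table
#'
#' @param annotation a `"residue_annotation"`.
#' @param track track name as in [import_scores()].
#' @return data.frame with columns `id`, `pos`, `value`.
#' @export
export_scores <- function(annotation, track) {
  v <- annotation[[track]]
  if (is.logical(v)) v <- as.integer(v)
  data.frame(id = annotation$id,
             pos = seq_len(annotation$length) - 1L,
             value = v, stringsAsFactors = FALSE)
}
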