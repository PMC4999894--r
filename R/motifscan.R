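# ELM-style linear-motif scanning.  Patterns are regular expressions over
# residue classes; the unknown residue X (the recoded stop, whose identity
# depends on the suppressor tRNA) is treated as a universal wildcard, so a
# pattern position that accepts any specific residue also accepts X.

#' Load a motif pattern set
#'
#' Reads a headered TSV with columns `elm_id`, `pattern`, `probability`
#' (chance-occurrence score in (0,1\]), `taxa` (comma-separated species
#' tags) and optionally `exemplar` (a literal string matching the pattern,
#' used for planting in synthetic data), and returns the species-specific
#' subset.  Every retained pattern is compiled once; a malformed expression
#' aborts the load naming the offending `elm_id`.
#'
#' @param table data.frame or TSV path.
#' @param species species tag to select on (a pattern is retained when its
#'   `taxa` field contains the tag).
#' @return data.frame of patterns for the species.
#' @export
load_patterns <- function(table, species) {
  if (is.character(table)) table <- .read_tsv(table)
  need <- c("elm_id", "pattern", "probability", "taxa")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop("pattern table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  taxa <- strsplit(table$taxa, ",[ ]*")
  keep <- vapply(taxa, function(t) species %in% t, logical(1))
  out <- table[keep, , drop = FALSE]
  rownames(out) <- NULL
  for (i in seq_len(nrow(out))) {
    ok <- tryCatch({
      regexpr(out$pattern[i], "ACDEFG", perl = TRUE)
      TRUE
    }, error = function(e) FALSE, warning = function(w) FALSE)
    if (!ok)
      stop(sprintf("pattern %s does not compile: %s",
                   out$elm_id[i], out$pattern[i]), call. = FALSE)
    if (any(out$probability <= 0 | out$probability > 1))
      stop("pattern probabilities must lie in (0,1]", call. = FALSE)
  }
  out
}

# Rewrite a motif regular expression so that X in the scanned sequence acts
# as a universal wildcard: literal residue letters become [aX], character
# classes [ABC] become [ABCX], negated classes [^ABC] become (?:[^ABC]|X).
# Quantifiers, groups, anchors and alternation pass through untouched.
.x_wildcard_pattern <- function(pat) {
  chars <- .chars(pat)
  out <- character(0)
  i <- 1L
  n <- length(chars)
  while (i <= n) {
    c <- chars[i]
    if (c == "[") {
      j <- i + 1L
      neg <- j <= n && chars[j] == "^"
      if (neg) j <- j + 1L
      body_start <- j
      # a literal ] directly after [ or [^ belongs to the class body
      if (j <= n && chars[j] == "]") j <- j + 1L
      while (j <= n && chars[j] != "]") j <- j + 1L
      if (j > n) stop("unterminated character class in pattern: ", pat,
                      call. = FALSE)
      body <- paste(chars[body_start:(j - 1L)], collapse = "")
      out <- c(out, if (neg) sprintf("(?:[^%s]|X)", body)
               else sprintf("[%sX]", body))
      i <- j + 1L
    } else if (c %in% LETTERS && c != "X") {
      out <- c(out, sprintf("[%sX]", c))
      i <- i + 1L
    } else {
      out <- c(out, c)
      i <- i + 1L
    }
  }
  paste(out, collapse = "")
}

#' Scan a protein for motif pattern matches
#'
#' Reports every match start: overlapping matches of the same pattern at
#' distinct starts are separate hits, and distinct patterns matching the
#' same span are separate hits.  At each start the leftmost match anchored
#' there is reported (one hit per pattern per start).  `X` in the sequence
#' matches any pattern position.
#'
#' @param seq protein sequence (20 residues + `X`).
#' @param patterns pattern data.frame from [load_patterns()].
#' @param protein_id identifier stored on the hits.
#' @return data.frame with columns `elm_id`, `protein_id`, `start`, `end`
#'   (0-based half-open), `probability`.
#' @export
scan_motifs <- function(seq, patterns, protein_id = "protein") {
  n <- nchar(seq)
  hits <- list()
  for (p in seq_len(nrow(patterns))) {
    pat <- .x_wildcard_pattern(patterns$pattern[p])
    anchored_end <- grepl("\\$$", pat)
    # anchor at every start: ^(?:pat) on each suffix
    apat <- paste0("^(?:", sub("^\\^", "", pat), ")")
    starts <- if (grepl("^\\^", patterns$pattern[p])) 0L else 0:(n - 1L)
    for (s in starts) {
      m <- regexpr(apat, substr(seq, s + 1L, n), perl = TRUE)
      if (m != -1L) {
        len <- attr(m, "match.length")
        if (len > 0L)
          hits[[length(hits) + 1L]] <-
            data.frame(elm_id = patterns$elm_id[p], protein_id = protein_id,
                       start = s, end = s + len,
                       probability = patterns$probability[p],
                       stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(hits))
    return(data.frame(elm_id = character(0), protein_id = character(0),
                      start = integer(0), end = integer(0),
                      probability = numeric(0), stringsAsFactors = FALSE))
  do.call(rbind, hits)
}

#' Classify motif hits by extension, disorder and binding-site overlap
#'
#' A hit is `in_extension` when at least one of its residues lies inside the
#' extension span (a motif completed by even a single extension residue
#' counts); it `overlaps_disorder` when at least one hit residue has a
#' disorder score at or above the reduced threshold `theta_elm_disorder`;
#' it `overlaps_binding` when at least one hit residue lies inside a
#' disordered binding site (binding score at or above the site threshold).
#'
#' @param hits hit data.frame from [scan_motifs()].
#' @param annotation full-protein `"residue_annotation"`.
#' @param ext_start,ext_end extension span (0-based half-open) on the
#'   annotated protein; use `NULL` for proteins without extension.
#' @param theta_elm_disorder inclusive disorder threshold for motif context.
#' @return the hits with logical columns `in_extension`,
#'   `overlaps_disorder`, `overlaps_binding` added.
#' @export
classify_hits <- function(hits, annotation, ext_start = NULL, ext_end = NULL,
                          theta_elm_disorder = annotation$config$theta_elm_disorder) {
  if (nrow(hits) &&
      (min(hits$start) < 0 || max(hits$end) > annotation$length))
    stop("hit span outside annotation", call. = FALSE)
  theta_b <- annotation$config$theta_binding
  res <- hits
  res$in_extension <- logical(nrow(hits))
  res$overlaps_disorder <- logical(nrow(hits))
  res$overlaps_binding <- logical(nrow(hits))
  for (i in seq_len(nrow(hits))) {
    idx <- (hits$start[i] + 1L):hits$end[i]
    res$in_extension[i] <- !is.null(ext_start) &&
      hits$start[i] < ext_end && hits$end[i] > ext_start
    res$overlaps_disorder[i] <- any(annotation$disorder[idx] >= theta_elm_disorder)
    res$overlaps_binding[i] <- any(annotation$binding[idx] >= theta_b)
  }
  res
}

#' Motif density per 100 residues
#'
#' @param n_motifs motif count.
#' @param n_residues residue count (must be positive).
#' @return list with `raw` (the exact density) and `rounded` (one decimal,
#'   halves away from zero, the convention used in reports).
#' @export
elm_density <- function(n_motifs, n_residues) {
  if (n_residues < 1) stop("n_residues must be >= 1", call. = FALSE)
  raw <- 100 * n_motifs / n_residues
  list(raw = raw, rounded = round_half_away(raw, 1))
}

#' Filter hits to low chance-occurrence probability
#'
#' Keeps hits with probability strictly below `p_max`; a hit at exactly the
#' cutoff is dropped.
#'
#' @param hits classified hit data.frame.
#' @param p_max strict probability cutoff.
#' @return filtered hits.
#' @export
low_probability_filter <- function(hits, p_max = 1e-3) {
  hits[hits$probability < p_max, , drop = FALSE]
}
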