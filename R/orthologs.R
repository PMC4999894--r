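# ortholog comparison: deterministic global alignment (Needleman-Wunsch
# with affine gaps, Gotoh's three-state recursion), separate CDS and
# extension alignments per ortholog pair, and shared-motif reporting under
# chance-probability filters.

.default_submat <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      m <- e$BLOSUM62
      keep <- c(AA20, "X")
      m <- m[keep, keep]
      m["X", ] <- 0   # the recoded stop is scored neutrally
      m[, "X"] <- 0
      cache <<- m
    }
    cache
  }
})

#' Alignment parameters
#'
#' @param submat substitution matrix (defaults to BLOSUM62 with the `X`
#'   row/column set to 0, so the unknown stop residue is scored neutrally).
#' @param gap_open penalty for opening a gap (positive).
#' @param gap_extend penalty per additional gap position (positive); a gap
#'   of length L costs `gap_open + (L - 1) * gap_extend`.
#' @return list of parameters.
#' @export
alignment_params <- function(submat = NULL, gap_open = 10, gap_extend = 0.5) {
  if (is.null(submat)) submat <- .default_submat()
  list(submat = submat, gap_open = gap_open, gap_extend = gap_extend)
}

#' Global pairwise alignment with affine gaps
#'
#' Needleman-Wunsch/Gotoh alignment maximising
#' `sum(substitution scores) - sum(gap costs)` with affine gap costs.
#' Traceback ties are broken deterministically: diagonal (match/mismatch)
#' is preferred over a gap in `a`, which is preferred over a gap in `b`.
#'
#' @param a,b peptide strings (non-empty).
#' @param params an [alignment_params()] list.
#' @return list with `aligned_a`, `aligned_b` (gap symbol `-`), `score`,
#'   `identity` (identical columns / alignment length, percent).
#' @export
global_align <- function(a, b, params = alignment_params()) {
  if (!nzchar(a) || !nzchar(b)) stop("empty input sequence", call. = FALSE)
  S <- params$submat
  go <- params$gap_open
  ge <- params$gap_extend
  ca <- .chars(a); cb <- .chars(b)
  n <- length(ca); m <- length(cb)
  if (!all(ca %in% rownames(S)) || !all(cb %in% rownames(S)))
    stop("sequence contains residues missing from the substitution matrix",
         call. = FALSE)
  NEG <- -1e15
  # M: a[i]~b[j]; GA: gap in a (consumes b[j]); GB: gap in b (consumes a[i])
  M <- GA <- GB <- matrix(NEG, n + 1, m + 1)
  M[1, 1] <- 0
  GA[1, 2:(m + 1)] <- -(go + (seq_len(m) - 1) * ge)
  GB[2:(n + 1), 1] <- -(go + (seq_len(n) - 1) * ge)
  sub <- matrix(S[ca, cb], n, m)
  # row-wise vectorized recursion; the gap-in-a state unrolls to a running
  # maximum because GA[i,j] = max_{k<j} (max(M,GB)[i,k] - go - (j-1-k)*ge)
  cols <- 2:(m + 1)
  for (i in 2:(n + 1)) {
    M[i, cols] <- pmax(M[i - 1, cols - 1], GA[i - 1, cols - 1],
                       GB[i - 1, cols - 1]) + sub[i - 1, ]
    GB[i, cols] <- pmax(M[i - 1, cols] - go, GB[i - 1, cols] - ge,
                        GA[i - 1, cols] - go)
    cm <- cummax(pmax(M[i, 1:m], GB[i, 1:m]) + (1:m) * ge)
    GA[i, cols] <- cm - go - (cols - 1) * ge
  }
  tol <- 1e-9
  pick <- function(vals) which(vals >= max(vals) - tol)[1]  # M > GA > GB
  i <- n + 1; j <- m + 1
  st <- pick(c(M[i, j], GA[i, j], GB[i, j]))
  score <- c(M[i, j], GA[i, j], GB[i, j])[st]
  ra <- rb <- character(n + m)
  k <- n + m + 1L
  while (i > 1 || j > 1) {
    k <- k - 1L
    if (st == 1L) {           # diagonal
      ra[k] <- ca[i - 1]; rb[k] <- cb[j - 1]
      tgt <- M[i, j] - sub[i - 1, j - 1]
      i <- i - 1; j <- j - 1
      st <- pick(c(if (abs(M[i, j] - tgt) < tol) 0 else NEG,
                   if (abs(GA[i, j] - tgt) < tol) 0 else NEG,
                   if (abs(GB[i, j] - tgt) < tol) 0 else NEG))
    } else if (st == 2L) {    # gap in a
      ra[k] <- "-"; rb[k] <- cb[j - 1]
      v <- GA[i, j]
      j <- j - 1
      st <- pick(c(if (abs(M[i, j] - go - v) < tol) 0 else NEG,
                   if (abs(GA[i, j] - ge - v) < tol) 0 else NEG,
                   if (abs(GB[i, j] - go - v) < tol) 0 else NEG))
    } else {                  # gap in b
      ra[k] <- ca[i - 1]; rb[k] <- "-"
      v <- GB[i, j]
      i <- i - 1
      # predecessor preference within a gap-in-b run: M > GB > GA
      st <- if (abs(M[i, j] - go - v) < tol) 1L
            else if (abs(GB[i, j] - ge - v) < tol) 3L else 2L
    }
  }
  ra <- ra[k:(n + m)]
  rb <- rb[k:(n + m)]
  ident <- 100 * mean(ra == rb & ra != "-")
  list(aligned_a = paste(ra, collapse = ""),
       aligned_b = paste(rb, collapse = ""),
       score = score, identity = ident)
}

#' Align an ortholog candidate pair
#'
#' Aligns the CDS regions of two readthrough candidates globally, then
#' aligns their extensions (from the recoded stop `X` onward) separately —
#' extension starts are generally not matched by the CDS alignment, so a
#' joint alignment would misplace them.  Identities are identical columns
#' over alignment length.
#'
#' @param cand_a,cand_b single-row candidate records (or lists) with
#'   `cds_protein` and `extension` fields.
#' @param params an [alignment_params()] list.
#' @return an object of class `"ortholog_pair"` with the two alignments and
#'   their percent identities.
#' @export
align_pair <- function(cand_a, cand_b, params = alignment_params()) {
  for (cand in list(cand_a, cand_b))
    if (is.null(cand$extension) || is.na(cand$extension) ||
        !nzchar(cand$extension))
      stop("candidate lacks an extension", call. = FALSE)
  cds_al <- global_align(cand_a$cds_protein, cand_b$cds_protein, params)
  ext_al <- global_align(cand_a$extension, cand_b$extension, params)
  structure(list(id_a = cand_a$id, id_b = cand_b$id,
                 cds_alignment = cds_al, extension_alignment = ext_al,
                 cds_identity = cds_al$identity,
                 extension_identity = ext_al$identity),
            class = "ortholog_pair")
}

#' @export
print.ortholog_pair <- function(x, ...) {
  cat(sprintf("ortholog_pair %s / %s: CDS identity %.1f%%, extension identity %.1f%%\n",
              x$id_a, x$id_b, x$cds_identity, x$extension_identity))
  invisible(x)
}

# map an ungapped sequence position (0-based) to its alignment column
.aln_columns <- function(aligned) {
  ch <- .chars(aligned)
  which(ch != "-")
}

#' Shared motifs between the extensions of an ortholog pair
#'
#' A motif type is shared when its `elm_id` occurs among the extension hits
#' of both partners with chance probability strictly below `p_max`.  With
#' `require_overlap`, the hit spans of the two partners must additionally
#' share at least one column of the extension alignment.  The report lists
#' shared ids at both the `p_max` cutoff and a ten-fold stricter one.
#'
#' @param pair an [align_pair()] result.
#' @param hits_a,hits_b hit data.frames for the two extensions, with spans
#'   on extension-local coordinates (0-based from the `X`).
#' @param p_max strict probability cutoff.
#' @param require_overlap demand positional overlap in alignment columns.
#' @return list with `shared` (ids at `p_max`), `shared_strict` (ids at
#'   `p_max / 10`), and the cutoffs used.
#' @export
shared_motifs <- function(pair, hits_a, hits_b, p_max = 1e-3,
                          require_overlap = FALSE) {
  shared_at <- function(cut) {
    ha <- hits_a[hits_a$probability < cut, , drop = FALSE]
    hb <- hits_b[hits_b$probability < cut, , drop = FALSE]
    ids <- intersect(ha$elm_id, hb$elm_id)
    if (!require_overlap || !length(ids)) return(ids)
    cola <- .aln_columns(pair$extension_alignment$aligned_a)
    colb <- .aln_columns(pair$extension_alignment$aligned_b)
    keep <- vapply(ids, function(id) {
      sa <- ha[ha$elm_id == id, , drop = FALSE]
      sb <- hb[hb$elm_id == id, , drop = FALSE]
      for (u in seq_len(nrow(sa))) for (v in seq_len(nrow(sb))) {
        colsu <- cola[(sa$start[u] + 1L):sa$end[u]]
        colsv <- colb[(sb$start[v] + 1L):sb$end[v]]
        if (length(intersect(colsu, colsv))) return(TRUE)
      }
      FALSE
    }, logical(1))
    ids[keep]
  }
  list(shared = shared_at(p_max),
       shared_strict = shared_at(p_max / 10),
       p_max = p_max, p_max_strict = p_max / 10)
}
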