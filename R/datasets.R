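# dataset assembly: proteome ingestion, candidate validation and filtering,
# and construction of the named segment sets (NonTRC, TRC, TRC_C, TRC_C30,
# TRC_E, RAND_C) with their _L and _BR variants.
#
# Coordinates are 0-based half-open on the EXTENDED protein: CDS residues
# occupy [0, L), the recoded stop X sits at position L, and the extension
# (which includes X and counts it toward its length) occupies [L, L + E).

#' Read a proteome from FASTA
#'
#' Identifiers are taken up to the first whitespace.  Proteins longer than
#' `max_len` residues are excluded at load (very long proteins are outside
#' the working range of the structural predictors).
#'
#' @param path FASTA file.
#' @param species species tag stored on the result.
#' @param max_len exclusion threshold in residues.
#' @return named character vector of sequences with attributes `species`
#'   and `n_excluded_too_long`.
#' @export
read_proteome <- function(path, species = "unknown", max_len = 10000) {
  aas <- Biostrings::readAAStringSet(path)
  ids <- sub("\\s.*$", "", names(aas))
  seqs <- as.character(aas)
  names(seqs) <- ids
  if (anyDuplicated(ids))
    stop(sprintf("duplicate protein ids in %s: %s", path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  if (any(nchar(seqs) == 0))
    stop("empty sequence(s) in proteome", call. = FALSE)
  too_long <- nchar(seqs) > max_len
  out <- seqs[!too_long]
  attr(out, "species") <- species
  attr(out, "n_excluded_too_long") <- sum(too_long)
  out
}

#' Write a proteome to FASTA
#'
#' @param proteome named character vector of sequences.
#' @param path output file.
#' @export
write_proteome <- function(proteome, path) {
  x <- Biostrings::AAStringSet(unclass(proteome))
  Biostrings::writeXStringSet(x, path, width = 60)
}

#' Read a readthrough-candidate table
#'
#' Tab-separated with header; expected columns `id`, `cds_protein`,
#' `extension` (peptide beginning with the recoded stop `X`), and optionally
#' `extension_nt`, `evidence` (`conserved`, `ribo_profiling` or `both`),
#' `readthrough_rate` (percent of CDS translation), `reads_rep1`,
#' `reads_rep2`.
#'
#' @param path TSV file.
#' @return data.frame of candidates.
#' @export
read_candidates <- function(path) {
  df <- .read_tsv(path)
  need <- c("id", "cds_protein", "extension")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("candidate table lacks column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  for (col in c("extension_nt", "evidence", "readthrough_rate",
                "reads_rep1", "reads_rep2"))
    if (is.null(df[[col]])) df[[col]] <- NA
  df
}

.filter_report <- function(n_in, kept_ids, exclusions) {
  structure(list(input = n_in, kept = length(kept_ids),
                 exclusions = exclusions), class = "filter_report")
}

#' @export
print.filter_report <- function(x, ...) {
  cat(sprintf("filter_report: %d in, %d kept, %d excluded\n",
              x$input, x$kept, nrow(x$exclusions)))
  if (nrow(x$exclusions))
    print(table(x$exclusions$reason))
  invisible(x)
}

#' Validate candidate identifiers against a proteome
#'
#' A candidate whose id resolves in the proteome is kept.  A candidate whose
#' id is absent is rescued if its CDS protein sequence is a perfect match to
#' a proteome entry of equal length, in which case it is remapped to that
#' entry's id; otherwise it is excluded (`id_not_found` when no sequence is
#' available for matching, `no_sequence_match` when matching failed).
#' Candidates whose CDS exceeds the proteome length cutoff are excluded as
#' `too_long`.
#'
#' @param candidates candidate data.frame (see [read_candidates()]).
#' @param proteome named character vector from [read_proteome()].
#' @param max_len length exclusion threshold (residues).
#' @return list with elements `candidates` (validated, possibly remapped)
#'   and `report` (a `filter_report`).
#' @export
validate_candidates <- function(candidates, proteome, max_len = 10000) {
  if (anyDuplicated(candidates$id))
    stop("duplicate candidate ids: ",
         paste(unique(candidates$id[duplicated(candidates$id)]),
               collapse = ", "), call. = FALSE)
  n_in <- nrow(candidates)
  excl <- data.frame(id = character(0), reason = character(0),
                     stringsAsFactors = FALSE)
  keep <- logical(n_in)
  by_seq <- NULL
  for (i in seq_len(n_in)) {
    id <- candidates$id[i]
    cds <- candidates$cds_protein[i]
    if (!is.na(cds) && nzchar(cds) && nchar(cds) > max_len) {
      excl <- rbind(excl, data.frame(id = id, reason = "too_long"))
      next
    }
    if (id %in% names(proteome)) {
      if (is.na(cds) || !nzchar(cds))
        candidates$cds_protein[i] <- unname(proteome[[id]])
      keep[i] <- TRUE
    } else if (!is.na(cds) && nzchar(cds)) {
      if (is.null(by_seq)) {
        by_seq <- names(proteome)
        names(by_seq) <- unname(unclass(proteome))
      }
      hit <- by_seq[cds]   # exact match implies equal length
      if (!is.na(hit)) {
        candidates$id[i] <- unname(hit)
        keep[i] <- TRUE
      } else {
        excl <- rbind(excl, data.frame(id = id, reason = "no_sequence_match"))
      }
    } else {
      excl <- rbind(excl, data.frame(id = id, reason = "id_not_found"))
    }
  }
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(candidates = out,
       report = .filter_report(n_in, out$id, excl))
}

#' Minimum-read filter for profiling-derived candidates
#'
#' Candidates carrying replicate read counts are kept only if BOTH
#' replicates show at least `min_reads` reads in the extension region
#' (boundary inclusive).  Rows without counts (e.g. candidates identified by
#' evolutionary conservation) pass through unfiltered.
#'
#' @param candidates candidate data.frame.
#' @param min_reads minimum reads per replicate.
#' @return list with `candidates` and `report`.
#' @export
apply_read_filters <- function(candidates, min_reads = 5) {
  r1 <- candidates$reads_rep1
  r2 <- candidates$reads_rep2
  if (any(stats::na.omit(c(r1, r2)) < 0))
    stop("negative read counts", call. = FALSE)
  has <- !is.na(r1) & !is.na(r2)
  keep <- !has | (r1 >= min_reads & r2 >= min_reads)
  keep[is.na(keep)] <- TRUE
  excl <- data.frame(id = candidates$id[!keep],
                     reason = rep("low_reads", sum(!keep)),
                     stringsAsFactors = FALSE)
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(candidates = out, report = .filter_report(nrow(candidates), out$id, excl))
}

.codons <- function(nt) {
  if (nchar(nt) %% 3 != 0)
    stop("extension_nt length not divisible by 3", call. = FALSE)
  substring(nt, seq(1, nchar(nt), 3), seq(3, nchar(nt), 3))
}

#' AUG-reinitiation filter
#'
#' Excludes candidates in which any of the first three in-frame extension
#' codons is ATG, since such an AUG could support translation reinitiation
#' rather than genuine readthrough.  If the supplied nucleotide string
#' begins with a stop codon (the recoded stop, matching the leading `X` of
#' the extension peptide) that codon is skipped and the next three codons
#' are checked.  Rows without `extension_nt` pass through with a warning.
#'
#' @param candidates candidate data.frame.
#' @return list with `candidates` and `report`.
#' @export
apply_aug_filter <- function(candidates) {
  nt <- candidates$extension_nt
  has <- !is.na(nt) & nzchar(nt)
  if (any(!has))
    warning(sprintf("%d candidate(s) lack extension_nt; passed through unchecked",
                    sum(!has)), call. = FALSE)
  bad <- vapply(seq_len(nrow(candidates)), function(i) {
    if (!has[i]) return(FALSE)
    cod <- .codons(toupper(nt[i]))
    if (cod[1] %in% c("TAA", "TAG", "TGA", "UAA", "UAG", "UGA"))
      cod <- cod[-1]
    any(utils::head(cod, 3) %in% c("ATG", "AUG"))
  }, logical(1))
  excl <- data.frame(id = candidates$id[bad],
                     reason = rep("aug_reinitiation", sum(bad)),
                     stringsAsFactors = FALSE)
  out <- candidates[!bad, , drop = FALSE]
  rownames(out) <- NULL
  list(candidates = out, report = .filter_report(nrow(candidates), out$id, excl))
}

#' Biological-relevance filter (suffix `_BR`)
#'
#' Keeps candidates whose evidence includes evolutionary conservation
#' unconditionally, and profiling-only candidates whose readthrough rate is
#' at least `min_rate` percent of the CDS translation rate (inclusive).
#'
#' @param candidates candidate data.frame.
#' @param min_rate minimum readthrough rate (percent).
#' @return list with `candidates` and `report`.
#' @export
filter_biologically_relevant <- function(candidates, min_rate = 1.2) {
  conserved <- !is.na(candidates$evidence) &
    candidates$evidence %in% c("conserved", "both")
  rate_ok <- !is.na(candidates$readthrough_rate) &
    candidates$readthrough_rate >= min_rate
  keep <- conserved | rate_ok
  excl <- data.frame(id = candidates$id[!keep],
                     reason = rep("low_rate", sum(!keep)),
                     stringsAsFactors = FALSE)
  out <- candidates[keep, , drop = FALSE]
  rownames(out) <- NULL
  list(candidates = out, report = .filter_report(nrow(candidates), out$id, excl))
}

# pick a RAND_C donor for one candidate: length within +/- tol of the
# extended candidate length, widening by 1-point steps up to tol_max.
.pick_donor <- function(target_len, donor_lens, used, tol, tol_max, rng_sample) {
  t <- tol
  repeat {
    ok <- which(!used & abs(donor_lens - target_len) <= t * target_len)
    if (length(ok)) return(ok[rng_sample(length(ok))])
    t <- t + 0.01
    if (t > tol_max + 1e-9) return(NA_integer_)
  }
}

#' Build the named segment datasets
#'
#' Constructs, on 0-based half-open extended-protein coordinates:
#' \describe{
#'   \item{NonTRC}{all proteome entries that are not candidate gene products
#'     (whole proteins).}
#'   \item{TRC}{candidate proteins without their extensions.}
#'   \item{TRC_C}{the C-terminal segment of each candidate CDS, of length
#'     `min(extension length, CDS length)`.}
#'   \item{TRC_C30}{the last `min(30, CDS length)` residues of each
#'     candidate CDS.}
#'   \item{TRC_E}{the extensions themselves (leading `X` included).}
#'   \item{RAND_C}{for each extended candidate, the C-terminus (of length
#'     `min(extension length, donor length)`) of one non-candidate donor
#'     whose length is within ±`tolerance` of the extended candidate's
#'     length, sampled without replacement; if no donor qualifies the
#'     tolerance widens in 1-percentage-point steps up to `tolerance_max`,
#'     beyond which an error names the candidate.}
#' }
#'
#' @param proteome named character vector.
#' @param candidates validated candidate data.frame.
#' @param tolerance,tolerance_max RAND_C length-matching tolerances
#'   (fractions of the extended candidate length).
#' @param match_extended if `FALSE`, match donors on the unextended CDS
#'   length instead.
#' @return an object of class `"segment_sets"`: a named list of data.frames
#'   with columns `protein_id`, `start`, `end`, `seq`, `candidate_id`.
#' @export
build_segment_sets <- function(proteome, candidates,
                               tolerance = 0.05, tolerance_max = 0.10,
                               match_extended = TRUE) {
  ids <- names(proteome)
  cand_ids <- candidates$id
  if (!all(cand_ids %in% ids))
    stop("candidates not in proteome (validate first): ",
         paste(setdiff(cand_ids, ids), collapse = ", "), call. = FALSE)
  non_ids <- setdiff(ids, cand_ids)

  seg_df <- function(pid, start, end, seq, cid = NA_character_)
    data.frame(protein_id = pid, start = start, end = end, seq = seq,
               candidate_id = cid, stringsAsFactors = FALSE)

  cds <- candidates$cds_protein
  ext <- candidates$extension
  L <- nchar(cds)
  E <- nchar(ext)

  non_seq <- unname(unclass(proteome)[non_ids])
  sets <- list(
    NonTRC = seg_df(non_ids, 0L, nchar(non_seq), non_seq),
    TRC = seg_df(cand_ids, 0L, L, cds, cand_ids),
    TRC_C = seg_df(cand_ids, L - pmin(E, L), L,
                   substr(cds, L - pmin(E, L) + 1L, L), cand_ids),
    TRC_C30 = seg_df(cand_ids, L - pmin(30L, L), L,
                     substr(cds, L - pmin(30L, L) + 1L, L), cand_ids),
    TRC_E = seg_df(cand_ids, L, L + E, ext, cand_ids)
  )

  donor_lens <- nchar(unclass(proteome)[non_ids])
  used <- logical(length(non_ids))
  target <- if (match_extended) L + E else L
  rc <- seg_df(character(0), integer(0), integer(0), character(0), character(0))
  for (i in seq_along(cand_ids)) {
    j <- .pick_donor(target[i], donor_lens, used, tolerance, tolerance_max,
                     function(n) sample.int(n, 1L))
    if (is.na(j))
      stop(sprintf("no RAND_C donor within ±%d%% for candidate %s (target length %d)",
                   round(100 * tolerance_max), cand_ids[i], target[i]),
           call. = FALSE)
    used[j] <- TRUE
    dl <- donor_lens[j]
    m <- min(E[i], dl)
    rc <- rbind(rc, seg_df(non_ids[j], dl - m, dl,
                           substr(proteome[[non_ids[j]]], dl - m + 1L, dl),
                           cand_ids[i]))
  }
  sets$RAND_C <- rc
  structure(sets, class = "segment_sets",
            candidates = candidates,
            tolerance = tolerance, match_extended = match_extended)
}

#' @export
print.segment_sets <- function(x, ...) {
  cat("segment_sets:\n")
  for (nm in names(x))
    cat(sprintf("  %-10s %5d segments, %8d residues\n", nm, nrow(x[[nm]]),
                sum(nchar(x[[nm]]$seq))))
  invisible(x)
}

#' Long-extension variants (suffix `_L`)
#'
#' Retains candidates whose extension length is at least `min_len` residues
#' (inclusive), together with their matched TRC_C, TRC_C30 and RAND_C
#' partner segments; the filtered sets get an `_L` suffix.
#'
#' @param sets a [build_segment_sets()] result.
#' @param min_len minimum extension length (residues, `X` included).
#' @return the input `segment_sets` with `TRC_E_L`, `TRC_C_L`, `TRC_C30_L`
#'   and `RAND_C_L` added.
#' @export
filter_long <- function(sets, min_len = 25) {
  stopifnot(inherits(sets, "segment_sets"), !is.null(sets$TRC_E))
  long_ids <- sets$TRC_E$candidate_id[
    (sets$TRC_E$end - sets$TRC_E$start) >= min_len]
  for (nm in c("TRC_E", "TRC_C", "TRC_C30", "RAND_C")) {
    if (is.null(sets[[nm]])) next
    sets[[paste0(nm, "_L")]] <-
      sets[[nm]][sets[[nm]]$candidate_id %in% long_ids, , drop = FALSE]
  }
  sets
}
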