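AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

#' Round half away from zero
#'
#' Rounds to `digits` decimals with halves moving away from zero, the
#' convention used for all percentages and motif densities in reports
#' (so 6.25 prints as 6.3, not 6.2).
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 1) {
  f <- 10^digits
  sign(x) * trunc(abs(x) * f + 0.5) / f
}

# split a protein string into single residues
.chars <- function(s) strsplit(s, "", fixed = TRUE)[[1]]

.check_residues <- function(seq, allow_x = TRUE, what = "sequence") {
  ch <- unique(.chars(seq))
  ok <- ch %in% c(AA20, if (allow_x) "X")
  if (!all(ok))
    stop(sprintf("%s contains invalid residue(s): %s", what,
                 paste(ch[!ok], collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

# windowed running mean with truncated terminal windows.
# width w: floor((w-1)/2) positions to the left, the rest to the right.
.window_mean <- function(x, w) {
  n <- length(x)
  if (w <= 1L || n == 1L) return(x)
  hl <- (w - 1L) %/% 2L
  hr <- w - 1L - hl
  cs <- c(0, cumsum(x))
  lo <- pmax(seq_len(n) - hl, 1L)
  hi <- pmin(seq_len(n) + hr, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

.read_tsv <- function(path) {
  utils::read.delim(path, header = TRUE, sep = "\t", quote = "",
                    stringsAsFactors = FALSE, comment.char = "#")
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
}

# maximal runs of TRUE in a logical vector, as 0-based half-open spans
.runs_true <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths
  cbind(start = starts[r$values], end = ends[r$values])
}
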