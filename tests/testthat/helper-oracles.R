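# independent oracles used across tests: these deliberately re-derive the
# quantities from first principles (enumeration, direct computation,
# exhaustive search) rather than calling the implementation under test.

# exact two-sided Mann-Whitney p by enumerating all group labelings
oracle_mw_exact <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  cmb <- combn(n1 + n2, n1)
  Us <- apply(cmb, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(Us <= U), mean(Us >= U)))
}

# direct (uncached, unvectorized) window composition entropy in bits
oracle_window_entropy <- function(window_chars) {
  win <- window_chars[window_chars != "X"]
  if (!length(win)) return(0)
  p <- table(win)
  p <- p / sum(p)
  -sum(p * log2(p))
}

# exhaustive-search optimal affine-gap global alignment score
oracle_align_score <- function(a, b, S, gap_open, gap_extend) {
  ca <- strsplit(a, "")[[1]]
  cb <- strsplit(b, "")[[1]]
  best <- -Inf
  rec <- function(i, j, sc, state) {
    if (i > length(ca) && j > length(cb)) {
      best <<- max(best, sc)
      return(invisible())
    }
    if (i <= length(ca) && j <= length(cb))
      rec(i + 1, j + 1, sc + S[ca[i], cb[j]], "M")
    if (j <= length(cb))
      rec(i, j + 1, sc - (if (state == "GA") gap_extend else gap_open), "GA")
    if (i <= length(ca))
      rec(i + 1, j, sc - (if (state == "GB") gap_extend else gap_open), "GB")
  }
  rec(1, 1, 0, "start")
  best
}

# score an emitted alignment directly from its gapped strings
oracle_score_alignment <- function(xa, xb, S, gap_open, gap_extend) {
  cx <- strsplit(xa, "")[[1]]
  cy <- strsplit(xb, "")[[1]]
  s <- 0; run <- ""
  for (k in seq_along(cx)) {
    if (cx[k] == "-") {
      s <- s - (if (run == "GA") gap_extend else gap_open); run <- "GA"
    } else if (cy[k] == "-") {
      s <- s - (if (run == "GB") gap_extend else gap_open); run <- "GB"
    } else {
      s <- s + S[cx[k], cy[k]]; run <- "M"
    }
  }
  s
}

AA <- c("A","C","D","E","F","G","H","I","K","L",
        "M","N","P","Q","R","S","T","V","W","Y")

random_peptide <- function(n) paste(sample(AA, n, TRUE), collapse = "")
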