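# segment- and residue-level statistics: structural profiles, Mann-Whitney
# (exact by enumeration for small samples, Edgeworth-corrected normal
# otherwise), Kruskal-Wallis with Dunn's post hoc, Yates-corrected
# goodness-of-fit chi-square on residue counts, Bonferroni thresholds,
# D'Agostino-Pearson normality, and amino-acid composition log-ratios.

.comparison_result <- function(property, groups, test, statistic, p_raw,
                               p_adjusted = p_raw, alpha_corrected = 0.05) {
  data.frame(property = property,
             groups = paste(groups, collapse = " vs "),
             test = test,
             statistic = statistic,
             p_raw = p_raw,
             p_adjusted = p_adjusted,
             alpha_corrected = alpha_corrected,
             significant = p_adjusted < alpha_corrected,
             stringsAsFactors = FALSE)
}

#' Structural profile of a segment
#'
#' Fractions of segment residues that are disordered (score at or above
#' `theta_disorder`), low-complexity, in regular secondary structure (H or
#' E), Pfam-annotated, and inside disordered binding sites.  The denominator
#' is the full segment length including any `X` residue; `X` itself is
#' never counted positive for the predicted properties (its scores are
#' propensity-mean placeholders, not predictions for a real residue).
#'
#' @param ann an excised (or full) `"residue_annotation"`.
#' @return one-row data.frame with the five fractions and `length`.
#' @export
profile_segment <- function(ann) {
  stopifnot(inherits(ann, "residue_annotation"))
  n <- ann$length
  if (n < 1) stop("zero-length segment", call. = FALSE)
  notx <- .chars(ann$sequence) != "X"
  cfg <- ann$config
  data.frame(
    id = ann$id,
    length = n,
    disordered = sum(ann$disorder >= cfg$theta_disorder & notx) / n,
    low_complexity = sum(ann$low_complexity & notx) / n,
    secondary_structure = sum(ann$ss_class %in% c("H", "E") & notx) / n,
    pfam = sum(ann$pfam) / n,
    binding_site = sum(ann$binding >= cfg$theta_binding & notx) / n,
    stringsAsFactors = FALSE)
}

# exact two-sided Mann-Whitney p by enumerating all C(n1+n2, n1) labelings
.mw_exact <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  cmb <- utils::combn(n1 + n2, n1)
  Us <- colSums(matrix(r[cmb], nrow = n1)) - n1 * (n1 + 1) / 2
  p <- min(1, 2 * min(mean(Us <= U), mean(Us >= U)))
  list(U = U, p = p)
}

# tie-corrected normal approximation with continuity correction and an
# Edgeworth kurtosis term.  The exact 4th cumulant of U under H0 (no ties)
# is kappa4 = -mn(N+1)(m^2+n^2+mn+N)/120.
.mw_approx <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  N <- n1 + n2
  r <- rank(c(a, b))
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  s2 <- n1 * n2 / 12 * (N + 1 - tie_term)
  if (s2 <= 0) return(list(U = U, p = 1))
  k4 <- -(n1 * n2 * (N + 1) / 120) * (n1^2 + n2^2 + n1 * n2 + N)
  Ul <- min(U, n1 * n2 - U)
  z <- (Ul + 0.5 - n1 * n2 / 2) / sqrt(s2)
  F <- stats::pnorm(z) - stats::dnorm(z) * (k4 / (24 * s2^2)) * (z^3 - 3 * z)
  list(U = U, p = min(1, max(0, 2 * F)))
}

#' Two-sided Mann-Whitney U test
#'
#' For samples where both sizes are at most `exact_max` the two-sided p is
#' computed exactly by full enumeration of all group labelings; for larger
#' samples a tie-corrected normal approximation with continuity correction
#' and an Edgeworth kurtosis refinement is used.
#'
#' @param a,b numeric samples (each non-empty).
#' @param property label for the result row.
#' @param groups length-2 character vector of group names.
#' @param alpha_corrected significance threshold recorded on the result.
#' @param exact_max largest per-group size for the exact path.
#' @return one-row `ComparisonResult` data.frame.
#' @export
mann_whitney <- function(a, b, property = "value",
                         groups = c("a", "b"), alpha_corrected = 0.05,
                         exact_max = 8) {
  if (!length(a) || !length(b)) stop("empty sample", call. = FALSE)
  res <- if (length(a) <= exact_max && length(b) <= exact_max)
    .mw_exact(a, b) else .mw_approx(a, b)
  .comparison_result(property, groups, "mann_whitney", res$U, res$p,
                     res$p, alpha_corrected)
}

#' Kruskal-Wallis with Dunn's post hoc
#'
#' Kruskal-Wallis H (tie-corrected, via [stats::kruskal.test()]); when its p
#' falls below `alpha`, Dunn's z-test is run for each requested pair with
#' the p-value adjusted by multiplying by the number of comparisons (capped
#' at 1), or by Holm's method.
#'
#' @param groups named list of at least three numeric samples.
#' @param alpha gate for running the post hoc.
#' @param pairs optional list of length-2 character vectors naming the
#'   pairs of interest (default: all pairs).
#' @param adjust `"bonferroni"` (multiply by m) or `"holm"`.
#' @param alpha_corrected significance threshold recorded on post-hoc rows.
#' @param property label for the result rows.
#' @return data.frame: the omnibus row followed by any post-hoc rows.
#' @export
kruskal_dunn <- function(groups, alpha = 0.05, pairs = NULL,
                         adjust = c("bonferroni", "holm"),
                         alpha_corrected = 0.05, property = "value") {
  adjust <- match.arg(adjust)
  if (length(groups) < 3)
    stop("fewer than 3 groups: use mann_whitney()", call. = FALSE)
  if (is.null(names(groups))) names(groups) <- paste0("g", seq_along(groups))
  kw <- stats::kruskal.test(unname(groups))
  H <- unname(kw$statistic)
  p_kw <- kw$p.value
  if (is.nan(H) || is.nan(p_kw)) {   # no variation anywhere: a perfect null
    H <- 0
    p_kw <- 1
  }
  out <- .comparison_result(property, names(groups), "kruskal_wallis",
                            H, p_kw, p_kw, alpha)
  if (is.na(p_kw) || p_kw >= alpha) return(out)

  x <- unlist(groups, use.names = FALSE)
  g <- rep(names(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  rbar <- tapply(r, g, mean)
  n <- tapply(r, g, length)
  ties <- table(r)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  if (is.null(pairs))
    pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  m <- length(pairs)
  praw <- vapply(pairs, function(pr) {
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / n[[pr[1]]] + 1 / n[[pr[2]]]))
    z <- (rbar[[pr[1]]] - rbar[[pr[2]]]) / se
    2 * stats::pnorm(-abs(z))
  }, numeric(1))
  padj <- if (adjust == "bonferroni") pmin(1, praw * m)
          else stats::p.adjust(praw, "holm")
  for (k in seq_along(pairs))
    out <- rbind(out, .comparison_result(property, pairs[[k]], "dunn",
                                         NA_real_, praw[k], padj[k],
                                         alpha_corrected))
  out
}

#' Yates-corrected goodness-of-fit chi-square on residue counts
#'
#' Compares the number of positively assigned residues in a segment set
#' against the expectation derived from a reference set's positive fraction:
#' a two-category goodness-of-fit with continuity correction,
#' `chi2 = sum_c (|O_c - E_c| - 0.5)^2 / E_c` over the positive and negative
#' categories, with `E_pos = ref_fraction * n` and df = 1.  The corrected
#' difference is not floored at zero, so a perfect fit yields a small
#' positive statistic rather than exactly zero.
#'
#' @param obs_positive observed positive residue count in the segment set.
#' @param n_segment total residue count of the segment set.
#' @param ref_fraction positive fraction of the reference set, in (0,1).
#' @param property,groups,alpha_corrected result-row metadata.
#' @return one-row `ComparisonResult` data.frame.
#' @export
yates_chi2_residues <- function(obs_positive, n_segment, ref_fraction,
                                property = "value",
                                groups = c("segment", "reference"),
                                alpha_corrected = 0.05) {
  if (n_segment < 1) stop("n_segment must be >= 1", call. = FALSE)
  if (ref_fraction <= 0 || ref_fraction >= 1)
    stop("ref_fraction must lie strictly between 0 and 1", call. = FALSE)
  e_pos <- ref_fraction * n_segment
  e_neg <- (1 - ref_fraction) * n_segment
  chi2 <- (abs(obs_positive - e_pos) - 0.5)^2 / e_pos +
    (abs((n_segment - obs_positive) - e_neg) - 0.5)^2 / e_neg
  p <- stats::pchisq(chi2, df = 1, lower.tail = FALSE)
  .comparison_result(property, groups, "yates_chi2", chi2, p, p,
                     alpha_corrected)
}

#' Bonferroni-corrected significance threshold
#'
#' @param alpha family-wise error rate.
#' @param m number of comparisons in the family (at least 1).
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha = 0.05, m) {
  if (m < 1) stop("m must be >= 1", call. = FALSE)
  alpha / m
}

#' D'Agostino-Pearson omnibus normality test
#'
#' K2 statistic combining the transformed skewness and kurtosis z-scores
#' (D'Agostino, Belanger & D'Agostino 1990), referred to a chi-square with
#' 2 df.  Used to justify the nonparametric testing route.
#'
#' @param x numeric sample of at least 20 observations.
#' @return one-row `ComparisonResult` data.frame.
#' @export
dagostino_pearson <- function(x) {
  n <- length(x)
  if (n < 20) stop("need at least 20 observations", call. = FALSE)
  if (stats::sd(x) == 0) stop("zero-variance sample", call. = FALSE)
  m <- mean(x)
  m2 <- mean((x - m)^2)
  m3 <- mean((x - m)^3)
  m4 <- mean((x - m)^4)
  g1 <- m3 / m2^1.5
  g2 <- m4 / m2^2 - 3
  # skewness transform
  y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  b2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (b2 - 1))
  d <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  z1 <- d * log(y / alpha + sqrt((y / alpha)^2 + 1))
  # kurtosis transform
  eb2 <- 3 * (n - 1) / (n + 1)
  vb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  b2s <- g2 + 3
  xk <- (b2s - eb2) / sqrt(vb2)
  beta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / beta1 * (2 / beta1 + sqrt(1 + 4 / beta1^2))
  z2 <- ((1 - 2 / (9 * A)) -
           ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))
  K2 <- z1^2 + z2^2
  p <- stats::pchisq(K2, df = 2, lower.tail = FALSE)
  .comparison_result("normality", "sample", "dagostino_pearson", K2, p)
}

#' Amino-acid composition log2 ratios
#'
#' Per-residue-type log2 frequency ratio of a segment set over a reference
#' set.  `X` residues are excluded from both numerator and denominator; a
#' pseudocount can be added to every residue count to handle residue types
#' absent from either set.
#'
#' @param set_seqs character vector of segment sequences.
#' @param ref_seqs character vector of reference sequences.
#' @param pseudocount count added to each of the 20 residue tallies.
#' @return named numeric vector of log2 ratios over the 20 residues.
#' @export
aa_composition_log2 <- function(set_seqs, ref_seqs, pseudocount = 0) {
  if (!length(set_seqs) || !length(ref_seqs))
    stop("both sets must be non-empty", call. = FALSE)
  count20 <- function(seqs) {
    ch <- unlist(strsplit(paste(seqs, collapse = ""), "", fixed = TRUE))
    tab <- table(factor(ch[ch != "X"], levels = AA20))
    as.numeric(tab) + pseudocount
  }
  cs <- count20(set_seqs)
  cr <- count20(ref_seqs)
  if (any(cr == 0) || any(cs == 0))
    stop("zero residue frequency; supply a pseudocount", call. = FALSE)
  out <- log2((cs / sum(cs)) / (cr / sum(cr)))
  names(out) <- AA20
  out
}
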