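# Propensity scales for the built-in structural predictors.  These are
# simplified, documented stand-ins: a windowed-propensity disorder scorer in
# the IUPred tradition, Chou-Fasman helix/strand propensities, and an
# ANCHOR-style interaction scale gated by disorder.  The pipeline contract
# (predict on the full extended protein, then excise segments; thresholds
# 0.5 for disorder, 0.4 for motif-context disorder) is what downstream
# statistics depend on, not the identity of the per-residue scorer, which is
# pluggable via import_scores().

# disorder propensity in [0,1]; disorder-promoting residues (P,E,S,Q,K,R,G)
# high, order-promoting aromatics/aliphatics low (TOP-IDP-like ranking).
.DISORDER_PROPENSITY <- c(
  W = 0.05, C = 0.08, F = 0.10, I = 0.12, Y = 0.15,
  V = 0.18, L = 0.20, M = 0.25, H = 0.30, T = 0.35,
  N = 0.38, A = 0.40, D = 0.45, G = 0.48, R = 0.55,
  K = 0.58, Q = 0.62, S = 0.65, E = 0.70, P = 0.75)

# Chou-Fasman helix propensities
.HELIX_PROPENSITY <- c(
  A = 1.42, C = 0.70, D = 1.01, E = 1.51, F = 1.13,
  G = 0.57, H = 1.00, I = 1.08, K = 1.16, L = 1.21,
  M = 1.45, N = 0.67, P = 0.57, Q = 1.11, R = 0.98,
  S = 0.77, T = 0.83, V = 1.06, W = 1.08, Y = 0.69)

# Chou-Fasman beta-strand propensities
.STRAND_PROPENSITY <- c(
  A = 0.83, C = 1.19, D = 0.54, E = 0.37, F = 1.38,
  G = 0.75, H = 0.87, I = 1.60, K = 0.74, L = 1.30,
  M = 1.05, N = 0.89, P = 0.55, Q = 1.10, R = 0.93,
  S = 0.75, T = 1.19, V = 1.70, W = 1.37, Y = 1.47)

# interaction propensity in [0,1]: residues frequently buried in interfaces
# when their context is disordered (aromatics, aliphatics, Arg/Lys).
.BINDING_PROPENSITY <- c(
  W = 0.95, F = 0.90, Y = 0.85, L = 0.80, I = 0.75,
  M = 0.70, V = 0.65, R = 0.60, K = 0.55, C = 0.55,
  H = 0.50, A = 0.45, Q = 0.40, T = 0.40, S = 0.35,
  N = 0.35, E = 0.30, G = 0.30, D = 0.25, P = 0.20)

#' Configuration for the built-in structural predictors
#'
#' Bundles the propensity scales, window widths, logistic calibrations and
#' decision thresholds used by [disorder_track()], [seg_lowcomplexity()],
#' [ss_track()], [binding_track()] and [annotate_protein()].  All windows
#' are truncated (never padded) at the termini.  The `X` residue standing
#' for the recoded stop codon is assigned the mean propensity of each scale
#' and is excluded from low-complexity composition vectors.
#'
#' @param disorder_propensity named numeric in \[0,1\] over the 20 residues.
#' @param disorder_window window width (residues) for the disorder scorer.
#' @param disorder_logistic_gain,disorder_logistic_center logistic mapping of
#'   the windowed mean propensity to a score in \[0,1\]; the center defaults
#'   to the mean of the propensity scale so an unbiased composition scores
#'   near 0.5.
#' @param seg_window SEG-style window width W (residues).
#' @param seg_trigger,seg_extend entropy thresholds K2(1) and K2(2) in bits:
#'   windows at or below `seg_trigger` trigger a low-complexity region, which
#'   extends over contiguous windows at or below `seg_extend`.
#' @param ss_helix_propensity,ss_strand_propensity named numeric scales.
#' @param ss_window window width for the secondary-structure scorer.
#' @param binding_propensity named numeric in \[0,1\].
#' @param binding_window,binding_logistic_gain,binding_logistic_center
#'   windowing and logistic calibration of the binding scorer.
#' @param theta_disorder threshold on the disorder score for a residue to
#'   count as disordered (inclusive).
#' @param theta_elm_disorder reduced disorder threshold used when asking
#'   whether a motif overlaps a disordered region, and as the disorder gate
#'   of the binding scorer (inclusive).
#' @param theta_binding threshold on the binding score defining disordered
#'   binding sites (inclusive).
#' @return an object of class `"predictor_config"` (a list).
#' @export
predictor_config <- function(disorder_propensity = .DISORDER_PROPENSITY,
                             disorder_window = 21,
                             disorder_logistic_gain = 20,
                             disorder_logistic_center = mean(disorder_propensity),
                             seg_window = 12,
                             seg_trigger = 2.2,
                             seg_extend = 2.5,
                             ss_helix_propensity = .HELIX_PROPENSITY,
                             ss_strand_propensity = .STRAND_PROPENSITY,
                             ss_window = 6,
                             binding_propensity = .BINDING_PROPENSITY,
                             binding_window = 9,
                             binding_logistic_gain = 20,
                             binding_logistic_center = 0.45,
                             theta_disorder = 0.5,
                             theta_elm_disorder = 0.4,
                             theta_binding = 0.5) {
  stopifnot(all(AA20 %in% names(disorder_propensity)),
            all(AA20 %in% names(ss_helix_propensity)),
            all(AA20 %in% names(ss_strand_propensity)),
            all(AA20 %in% names(binding_propensity)),
            seg_trigger <= seg_extend,
            theta_disorder > 0, theta_disorder < 1,
            theta_elm_disorder > 0, theta_elm_disorder < 1,
            theta_binding > 0, theta_binding < 1)
  structure(list(
    disorder_propensity = disorder_propensity[AA20],
    disorder_window = as.integer(disorder_window),
    disorder_logistic_gain = disorder_logistic_gain,
    disorder_logistic_center = disorder_logistic_center,
    seg_window = as.integer(seg_window),
    seg_trigger = seg_trigger,
    seg_extend = seg_extend,
    ss_helix_propensity = ss_helix_propensity[AA20],
    ss_strand_propensity = ss_strand_propensity[AA20],
    ss_window = as.integer(ss_window),
    binding_propensity = binding_propensity[AA20],
    binding_window = as.integer(binding_window),
    binding_logistic_gain = binding_logistic_gain,
    binding_logistic_center = binding_logistic_center,
    theta_disorder = theta_disorder,
    theta_elm_disorder = theta_elm_disorder,
    theta_binding = theta_binding), class = "predictor_config")
}
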