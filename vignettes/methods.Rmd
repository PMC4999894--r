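---
title: "Profiling readthrough extensions: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Profiling readthrough extensions: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trextend)
```

## The analytical model

Stop-codon readthrough appends a C-terminal extension to a protein: the
ribosome decodes the stop codon as an amino acid (represented throughout as
the unknown residue `X`, because its identity depends on the suppressor
tRNA) and continues to the next in-frame stop.  The scientific question the
package addresses is whether these extensions differ structurally and
functionally from ordinary C-termini: are they more disordered, more
repetitive, richer in short linear interaction motifs, and are they
conserved between orthologs?

The analysis is a contrast between named segment datasets drawn on 0-based
half-open coordinates of the *extended* protein (CDS occupies `[0, L)`, the
recoded stop sits at `L`, the extension occupies `[L, L+E)` and includes
the `X`):

* **TRC_E** — the extensions themselves;
* **TRC_C** — the C-terminus of each candidate CDS, of length equal to its
  extension (truncated to the whole CDS when the extension is longer);
* **TRC_C30** — the last 30 CDS residues;
* **RAND_C** — for each extended candidate, the C-terminus of a
  non-candidate protein whose length is within ±5 % of the extended
  candidate's length, sampled without replacement;
* **NonTRC** — the rest of the proteome.

`_L` variants keep extensions of at least 25 residues (inclusive; the
threshold is configurable because printed sources are ambiguous between
"minimum 25" and "> 25"), and `_BR` keeps candidates with conservation
evidence or a readthrough rate of at least 1.2 % of CDS translation.
Candidates identified from profiling data are further filtered to at least
5 reads in the extension in *both* replicates, and candidates whose first
three in-frame extension codons contain an AUG are excluded as possible
reinitiation artifacts.  When the supplied nucleotide string begins with
the recoded stop codon itself, that codon is skipped before the
three-codon check, which keeps the codon count equal to the extension
length (the `X` counts toward both).

## Predict on the full protein, then excise

All per-residue tracks are computed once on the complete extended protein
and segment values are *excised* from the stored tracks, never re-predicted
on the isolated segment.  This matters because windowed scores near a
segment border depend on sequence context; `excise()` therefore returns
stored values and is idempotent, and a test asserts the excised values are
not equal to a re-prediction on the isolated fragment.

The built-in scorers are deliberately simplified, documented stand-ins with
the same interface as the standard tools they emulate, and every track can
be replaced by imported per-residue tables (`import_scores()`), e.g. from
genuine IUPred/PSIPRED/ANCHOR/SEG/PfamScan runs:

* **Disorder** — a logistic of the windowed mean (default window 21
  residues, truncated at termini) of a 20-residue disorder propensity scale
  in `[0,1]` that ranks P, E, S, Q, K, R as disorder-promoting and
  W, C, F, I, Y as order-promoting.  The logistic center defaults to the
  scale mean, so an unbiased composition scores near 0.5; the gain (20)
  makes the score cross 0.5 sharply where the windowed propensity crosses
  the center.  A residue is *disordered* at score ≥ 0.5; motif context
  uses the reduced threshold ≥ 0.4.
* **Low complexity** — Shannon entropy `K2` (bits) of each 12-residue
  window's composition with a trigger/extend pair of thresholds
  (2.2 / 2.5 bits): windows at or below the trigger seed a region, which
  extends across contiguous windows at or below the extension threshold.
  This is a dialect of the classic segmentation without the final
  minimal-probability refinement, which is not needed when the output is a
  residue fraction.  `X` occupies a position but is excluded from the
  composition vector, so the unknown residue cannot inflate window
  complexity.
* **Secondary structure** — windowed mean Chou–Fasman helix and strand
  propensities; class is the argmax of the two means when it exceeds 1.0,
  else coil, with ties resolved to helix.  The window default is 6; an
  even width is applied asymmetrically (2 left, 3 right of the residue).
* **Disordered binding sites** — an interaction-propensity logistic gated
  by the disorder track at the reduced 0.4 threshold, in the spirit of
  ANCHOR: only residues in a loosely disordered context can score as
  binding-capable, and a *binding site* is a maximal run with score ≥ 0.5.
* **Pfam occupancy** — not predicted: annotation spans are supplied as
  input and unioned; all entity types are accepted.

`X` is assigned the mean of each propensity scale, so all score tracks are
unchanged if `X` is replaced by a hypothetical mean-propensity residue; in
segment statistics `X` stays in denominators but never counts as a
positive residue, a conservative rule made explicit because printed
sources are silent on it.

## Motif scanning

Patterns are ELM-style regular expressions with chance-occurrence
probabilities and species tags.  Scanning reports every distinct match
start (overlapping matches of the same pattern are separate hits, as are
different patterns on the same span), because published motif counts are
pattern counts, not per-position unique counts.  `X` in a sequence acts as
a universal wildcard — literal positions, character classes and negated
classes all accept it — since the decoded residue is tRNA-dependent.  A
hit belongs to an extension if at least one residue overlaps it (a motif
completed by a single extension residue counts); it overlaps disorder or a
binding site under the same one-residue rule with inclusive thresholds.
Densities are reported per 100 residues, rounded half-away-from-zero to
one decimal (so 6.25 prints as 6.3); raw values are retained.  The
reporting filter keeps hits with probability strictly below 1e-3, with
1e-4 as the stricter comparison point.

## Statistics

* **Mann–Whitney U** (two-sided) for pairwise segment contrasts.  With
  both samples of size ≤ 8 the p-value is exact by full enumeration of all
  labelings.  The large-sample path is a tie-corrected normal
  approximation with continuity correction plus an Edgeworth kurtosis
  term using the exact fourth cumulant of U under the null,
  `κ4 = −mn(N+1)(m²+n²+mn+N)/120`; the refinement brings the
  approximation within 1e-3 of enumeration at the path boundary
  (samples of 7–8), where the plain normal approximation errs by ~0.01.
* **Kruskal–Wallis + Dunn** for three-way contrasts (TRC_E vs RAND_C vs
  TRC_C), with Dunn's two-sided z-tests run only when the omnibus p falls
  below alpha and adjusted by multiplying by the number of comparisons
  (capped at 1); Holm is available.
* **Residue-level Yates chi-square** — a two-category goodness-of-fit: the
  observed count of positively assigned extension residues against the
  expectation `ref_fraction × n`, with the continuity-corrected form
  `Σ (|O−E|−0.5)²/E`, df = 1.  The corrected difference is deliberately
  not floored at zero so the statistic matches the stated closed form
  exactly (a perfect fit gives a small positive value).  A 2×2
  contingency reading of the same comparison was considered and rejected
  as the default because the stated procedure defines an *expected value*
  from the reference fraction, which is the goodness-of-fit formulation.
* **Bonferroni families** — the segment-level design divides alpha by 4
  (one per structural property, giving 0.0125) and the residue-level
  design by 8 (4 properties × 2 reference sets, giving 0.00625).  Both
  family sizes are explicit configuration, since the two designs imply
  different families.
* **D'Agostino–Pearson K²** documents the non-normality that justifies the
  nonparametric route; the implementation follows the 1990
  skewness/kurtosis transforms and matches an independent reference
  implementation to six decimals on frozen samples.

GO enrichment corrects for the length bias of readthrough candidates by
sampling one non-candidate within ±5 % of each candidate's *unextended*
length (the gene-level question concerns the protein, not the extension)
and testing each term with an upper-tail hypergeometric p in the universe
`study ∪ background`, Benjamini–Hochberg adjusted.  The ±5 % tolerance
widens in 1-point steps to at most ±10 % before failing loudly — the
matching policy is explicit because silent fallbacks would bias the
background.  For RAND_C construction the matching length is the
*extended* candidate length, following the wording of the source
procedure; both choices are configurable.

Ortholog pairs are aligned CDS-to-CDS and extension-to-extension
*separately*, since extension starts are rarely matched by a joint
alignment.  The aligner is a deterministic Needleman–Wunsch/Gotoh with
affine gaps (BLOSUM62, open 10, extend 0.5, `X` scored 0 against
everything) and a fixed tie order (diagonal over gap-in-a over gap-in-b);
pairwise alignment is exactly what a multiple-alignment tool reduces to
for two sequences, and determinism makes the exhaustive-search oracle
test meaningful.  Shared motifs default to `elm_id` co-occurrence in both
extensions below the probability cutoff, without demanding positional
overlap (the positional criterion is available as an option), because
motif conservation in barely alignable extensions is a type-level
question.

## What the synthetic generator emulates

`generate_bundle()` produces a proteome with log-normal lengths (default
meanlog `log(400)`, sdlog 0.6), candidates with extensions of log-normal
length (meanlog `log(30)`, sdlog 0.8, minimum 2 including the `X`),
composition regimes (`fly_like` doubles P, Q, R, H, S; `yeast_like`
doubles Y, L, I, F, C and halves A, G, D, E, Q; `neutral` is uniform
1/20), planted motif exemplars, a planted GO fold, readthrough rates
log-uniform on [0.1, 10] % (spanning the 1.2 % relevance cut from both
sides), negative-binomial replicate read counts (mean 50, size 5), and
ortholog pairs built by substituting a shared ancestor CDS to a target
identity with independently drawn extensions.  Candidate genes are drawn
from the central 80 % of the length distribution so that ±5–10 %
length-matched controls exist at desk scale; real proteomes are two
orders of magnitude larger and do not need this restriction.

`disorder_shift` plants a disordered-fraction difference by mixing the
extension composition with a uniform distribution over the
disorder-promoting residues R, K, Q, S, E, P.  The mixing weight is not a
tuned constant: it is derived in closed form from the propensity scale by
a Gaussian approximation of the window mean (the disordered fraction is
the probability that a window mean exceeds the logistic center) together
with a junction-attenuation factor for the part of each window that
reaches into the untilted CDS.  The shift is planted *on top of* the
regime composition — a fly-like regime is already disorder-enriched
through its composition bias, exactly as disorder-promoting composition
is what makes real fly extensions disordered — so the realized
extension-vs-control difference is the regime's own offset plus the
configured shift, and is strictly monotone in the parameter.

What the generator does **not** emulate: nucleotide-level evolution
(ortholog extensions are independent, mirroring the unconserved-extension
finding without an indel model), ribosome-profiling reads along
transcripts (rates and counts are drawn, not simulated from coverage),
domain architecture (Pfam spans are inputs), and any correlation between
neighbouring residues beyond what planted exemplars introduce.  Passing
recovery tests on this generator therefore demonstrates that the pipeline
measures what it claims on data with known ground truth — not that the
simplified scorers reproduce IUPred/PSIPRED/ANCHOR outputs on real
proteins, for which the score-import path exists.

## Problem sizes and calibration experiments

The test suite runs its recovery experiments at desk scale, chosen so each
design has clear statistical margin: the planted-shift power experiment
uses 200 extensions against 200 matched controls per replicate over 100
seeded replicates (800-protein proteomes); the null calibration uses 40
against 40 over 500 replicates (300-protein proteomes) and checks the
rejection rate at the corrected 0.0125 threshold; GO recovery uses 200
candidates with a 20-term map and a planted fold of 3 over 100
replicates.  The null-calibration bundles plant *nothing* — no motif
exemplars and no composition tilt — because exemplars are literal
sequence insertions whose composition is not neutral by design; a null
that included them would measure their side effect rather than the
test's calibration.  Where a degenerate draw makes ±10 % control
matching impossible (an extreme-length tail candidate on a small
synthetic proteome), the replicate is deterministically re-seeded; the
event carries no information about the contrast under study.

## Known limitations

* The propensity-based scorers are interface-compatible stand-ins; their
  absolute disorder/structure calls on real sequences should not be
  compared against the original predictors' outputs except through the
  import path.
* Flat GO term sets: no ancestor propagation along the ontology graph.
* The exact-enumeration Mann–Whitney path is combinatorial and capped at
  samples of 8; above that the Edgeworth-corrected approximation is used.
* Proteins longer than 10,000 residues are excluded at load, matching the
  working range of the emulated predictors.
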