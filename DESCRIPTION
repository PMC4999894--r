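Package: trextend
Title: Structure-Function Profiling of Translational Readthrough Extensions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for profiling the structural and interaction properties of
    C-terminal protein extensions generated by stop-codon readthrough.
    Assembles candidate and matched-control segment datasets from a proteome
    and a readthrough-candidate table, computes per-residue structural tracks
    (intrinsic disorder, low sequence complexity, secondary structure,
    disordered binding propensity, Pfam occupancy) on full-length extended
    proteins and excises segment views, scans for short linear motifs with
    disorder and binding-site overlap classification, runs segment- and
    residue-level nonparametric statistics with multiple-testing control,
    performs GO term enrichment against a length-matched sampled background,
    and compares ortholog extension conservation by global alignment.  A
    self-contained synthetic-proteome generator with planted effects makes
    every stage testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Biostrings,
    stats,
    utils
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
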