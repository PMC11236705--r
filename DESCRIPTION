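Package: solufold
Title: Hallucination-Based Design of Soluble Membrane-Protein Analogues
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Gradient-descent sequence design ("hallucination") of soluble
    analogues of integral membrane protein folds against a pluggable
    structure-predictor ensemble. Optimizes a position-specific scoring
    matrix under a composite loss (frame-aligned Ca error, distogram cross
    entropy, pLDDT and pTM confidence penalties), redesigns backbones with a
    biased inverse-folding sampler with fixed functional positions, and
    scores designs with a structural and sequence metrics suite (TM-score,
    mean/rms Ca and full-atom deviation, Shrake-Rupley solvent accessibility,
    DSSP-style secondary structure, layer classification, surface
    hydrophobic fraction, secondary-structure contact order, BLAST-based
    sequence novelty). Includes epitope transplantation onto designed
    scaffolds, a deterministic differentiable toy folder standing in the
    structure-predictor role, and an ideal-geometry fixture generator so the
    whole pipeline runs at desk scale without downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    bio3d,
    jsonlite,
    yaml,
    stats,
    utils,
    graphics,
    tools,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
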