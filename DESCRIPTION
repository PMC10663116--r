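Package: paleodup
Title: Gene-Duplication Analysis: Ka/Ks, Synteny, WGD Dating, and
    Promoter Motif Enrichment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Toolkit for duplication-centric genome analysis in plants:
    Nei-Gojobori (1986) synonymous/nonsynonymous substitution estimation on
    codon alignments with Jukes-Cantor correction, collinear (syntenic) block
    chaining and syntenic depth ratios, tandem-duplicate detection and
    duplicate-origin classification, Ks-peak mixture modelling with
    molecular-clock dating of whole-genome duplications, diagnostic-residue
    plus diel-expression classification of C4- and CAM-specific gene copies,
    and promoter motif scanning with exact score p-values and Fisher/FDR
    enrichment. Includes a synthetic-genome simulator that plants WGD blocks,
    tandem arrays, diel expression phases and promoter motifs with known
    ground truth, so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    Rcpp,
    mclust,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
LinkingTo:
    Rcpp
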