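Package: f1proteome
Title: Genetic Architecture of Brain Protein Expression in Reciprocal F1 Hybrid Crosses
Version: 1.0.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Analysis workflow for tandem-mass-tag (TMT) proteomics of two
    inbred mouse strains (C57BL/6J and DBA/2J) and their reciprocal F1
    hybrids. Implements PSM-to-protein quantification (isotope-impurity
    correction, intensity filtering, loading normalisation, protein
    roll-up), moderated differential expression and single-parent
    expression screens, dominance/additivity statistics and broad-sense
    heritability from a REML variance-component model with pedigree-derived
    additive and dominance relatedness matrices, proteogenomic enumeration
    of allele-distinguishing tryptic variant peptides, and classification
    of allele-specific expression into cis, trans, compensatory, conserved
    and unexpected-bias regulation at both the protein and transcript
    level. A synthetic-data generator emulates the full study design so
    every stage is testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    limma,
    Biostrings,
    yaml,
    jsonlite
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
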