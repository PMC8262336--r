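Package: myoquiesce
Title: Molecular Phenotyping of Myometrium as Quiescent or Nonquiescent
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Classifies bulk RNA-seq profiles of human myometrium into
    quiescent (Q) and nonquiescent (NQ) contractile phenotypes. Provides
    semiquantitative clinical phenotype scoring, a simplified
    negative-binomial differential-expression stage for deriving the
    labor-associated transcript signature, PCA projection of unlabeled
    samples with nearest-centroid phenotype calling, permutation-based
    gene-set enrichment with overlap-coefficient edges, and a parsimonious
    two-gene ATP2B4/ATP2A2 expression-ratio classifier with ROC threshold
    selection from both RNA-seq counts and comparative-Ct qPCR data. A
    seeded synthetic-cohort generator (counts, qPCR Ct values, clinical
    covariates) makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    stats,
    utils,
    Matrix,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
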