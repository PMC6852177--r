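Package: ringwas
Title: Functional Multilocus Association Mapping for Annual-Ring Traits
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Genome-wide association for longitudinal wood-property traits
    measured over annual growth rings. Per-ring family breeding values are
    estimated by REML/BLUP from a joint-site mixed model, summarized into four
    latent traits by a two-knot linear spline, and mapped against SNP dosages
    with a multilocus LASSO under stability selection, controlling the
    expected number of false positives. Includes genotype quality control,
    principal-component covariates with Tracy-Widom significance, zygotic
    linkage-disequilibrium decay (Hill-Weir) fitting, mode-of-inheritance
    classification from genotype-class means, and a synthetic-data generator
    emulating a two-site half-sib progeny trial with admixed population
    structure and contig-scale LD.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    minpack.lm,
    stats,
    utils,
    vcfR,
    yaml
LinkingTo: Rcpp
Suggests:
    glmnet,
    lme4,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
NeedsCompilation: yes
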