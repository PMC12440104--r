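Package: pgin
Title: Placental Genomic Instability from Expressed Somatic Variants
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An analysis pipeline for genomic instability in placental
    transcriptomes. Starting from annotated somatic variant tables,
    per-sample genome-coverage histograms, and a gene expression matrix,
    the package applies a rare/damaging variant filter cascade, computes a
    per-sample genomic-instability score (expressed mutational burden per
    covered megabase), decomposes 96-context single-base-substitution
    catalogs into mutational signatures by non-negative matrix
    factorization, scores hypoxia gene signatures by median
    dichotomization, and relates these features to pregnancy outcomes
    (preeclampsia, maternal vascular malperfusion, small-for-gestational-age)
    through gestational-age-to-event Cox models, exact enrichment tests,
    and cross-validated k-nearest-neighbor classification. A synthetic
    cohort generator with planted effect sizes makes every stage testable
    without access to restricted sequencing data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    survival,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    pROC,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
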