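Package: survewas
Title: Survival EWAS of Methylation Arrays with SVD Confounder Screening
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Epigenome-wide association analysis of Infinium-style DNA
    methylation beta-value matrices against a time-to-event outcome.
    Provides sample and probe quality control, inter-array quantile
    normalisation, removal of the dominant mean-profile component, a
    permutation-null test for the significance of singular values with a
    component-by-phenotype association screen, per-CpG multivariate Cox
    proportional-hazards regression with Storey q-value false discovery
    rate control, combination of proximal CpG pairs, and a synthetic-data
    generator with known ground truth for validating the whole pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    jsonlite,
    stats,
    utils,
    graphics
Suggests:
    testthat (>= 3.0.0),
    withr,
    limma
Config/testthat/edition: 3
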