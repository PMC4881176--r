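Package: cnvfocal
Title: Spectral Decomposition of Copy-Number Profiles into Focal and
    Broad Components
Version: 1.0.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Separates somatic copy-number profiles into focal and broad
    components by two-scale running-median filtering, calls per-site
    gain/neutral/loss states against a robust noise estimate, locates
    recurrent focal peaks across a tumor cohort with bootstrap confidence
    intervals for their positions, filters germline copy-number
    polymorphisms using matched normal tissue, tests the association of
    focal gains and losses with oncogenes and tumor-suppressor genes, and
    provides a simulation framework to measure detection sensitivity and
    specificity.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    optparse,
    yaml
Config/testthat/edition: 3
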