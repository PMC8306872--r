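Package: nilcontrast
Title: Contrast Filtering of Near-Isogenic-Line Root Transcriptomes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Hypothesis-driven contrast filtering for FPKM expression tables from
    paired near-isogenic lines (NILs) assayed under a two-genotype by two-treatment
    design, built around a durum wheat cadmium-accumulation study design (low-Cd and
    high-Cd NILs, with and without cadmium). Provides replicate-level expression and
    metadata I/O, Welch t-test differential calling with Benjamini-Hochberg false
    discovery control and compound DEG flags, eight genotype-by-treatment set
    filters (genotype-exclusive, baseline-biased, genotype-specific and shared
    cadmium responses, strongly asymmetric induction, and annotation-matched shared
    regulators), coefficient-of-variation ranking of reference-gene candidates for
    qRT-PCR normalisation, replicate-correlation and clustering quality control,
    hypergeometric over-representation of annotation categories, and a synthetic
    FPKM generator that plants each gene class with known truth for end-to-end
    validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    pheatmap
Config/testthat/edition: 3
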