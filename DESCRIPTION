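Package: lipidews
Title: Sequencing-Based Epigenome-Wide Association of Plasma Lipids in
    Regulatory Elements
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for epigenome-wide association studies of plasma lipid
    traits (triglycerides, HDL-C, LDL-C, total cholesterol) from targeted
    bisulfite sequencing of regulatory elements. Covers strand merging and
    site-level quality control of per-CpG read counts, coverage-weighted
    binomial regression of methylation on lipid levels, empirical-null
    recalibration of test statistics via a constrained Gaussian-mixture EM,
    Storey q-values and per-trait Bonferroni thresholds, positional mapping
    of CpGs within low-methylated and unmethylated regions, cross-tissue
    region-level replication with direction-of-effect classes, fine-mapping
    contrasts against array-resolution CpGs, cis methylation QTL and
    methylation-expression integration, and a fully synthetic cohort
    generator with planted effects for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    graphics,
    tools,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
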