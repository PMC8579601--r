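Package: ergogwas
Title: Submaximal Fitness Phenotypes, Activity QC and Sex-Stratified
    Association at Desk Scale
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Derives cardiorespiratory fitness phenotypes (extrapolated
    relative power and heart-rate slope) from raw submaximal cycle
    ramp-test traces with full QC provenance, applies wrist-worn
    accelerometer inclusion filters, residualizes traits on covariate
    sets, runs per-variant association stratified by sex, reduces
    results by p-value-informed LD clumping, meta-analyses male/female
    effect pairs with Cochran's Q and I-squared heterogeneity
    statistics, and tabulates disease-diagnosis frequency by phenotype
    decile. A fully synthetic cohort generator with known ground truth
    (heart-rate response, LD-blocked genotypes, causal variant effects,
    disease liability) makes every stage testable without access to
    restricted cohort data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    data.table,
    ggplot2,
    jsonlite,
    signal,
    stats,
    tools,
    utils,
    vcfR,
    yaml
Suggests:
    metafor,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
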