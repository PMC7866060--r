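Package: sevscan
Title: Stochastic Epigenetic Variant Detection in Methylation Array Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Single-case analysis of DNA-methylation (450K-style) beta-value
    matrices. Detects Stochastic Epigenetic Variants (SEVs) as beta-values
    falling outside Tukey fences built from a healthy-control reference
    (Q1 - k*IQR, Q3 + k*IQR, k = 3), filters isolated calls with a sliding
    window cumulative hypergeometric enrichment scan over the probe manifest,
    subtracts deregulations seen in controls, groups the surviving calls into
    per-sample deregulated gene loci, and compares per-sample SEV burdens
    between groups with a covariate-adjusted count GLM. Also includes probe
    quality-control filtering, quantile normalization, a minimal group-level
    differential methylation surface, and a synthetic cohort generator with
    known injected epivariants for validation.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    stats,
    utils,
    data.table,
    jsonlite,
    limma,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
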