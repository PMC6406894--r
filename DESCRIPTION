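Package: clonehet
Title: Clonal Heterogeneity Characterisation from Multi-Omic Tumour Profiles
Version: 0.1.0
Authors@R:
    person("clonehet", "maintainers", email = "devnull@example.org", role = c("aut", "cre"))
Description: Characterises intratumoural clonal heterogeneity from multi-sample
    tumour cohorts (one bulk tumour, matched normal, and single-cell-derived
    clonal lines). Implements rule-based high-confidence somatic variant
    filtering with per-rule fail reasons, variant-allele-frequency matrix
    construction and trunk/shared/private classification of SNVs and structural
    variants, copy-number state summaries with whole-genome-duplication
    detection and ploidy correction, CpG methylation beta-value processing
    (coverage filtering, missing-aware quantile normalisation, imputation,
    variable-probe selection), TMM expression normalisation with fold-change
    flagging, SNP-array genotype concordance and LogR probe selection, and
    hierarchical sample-relationship clustering with Newick export. A seeded
    synthetic-cohort generator with full clonal ground truth exercises the
    pipeline end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    ape,
    data.table,
    GenomicRanges,
    IRanges,
    S4Vectors
Suggests:
    testthat (>= 3.0.0),
    withr,
    edgeR,
    limma,
    VariantAnnotation,
    optparse
Config/testthat/edition: 3
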