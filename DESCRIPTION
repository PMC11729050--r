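Package: armloh
Title: Arm-Level Imbalance, LOH and Copy-Number Pattern Analysis from
    Targeted SNP Panels
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tumor-only analysis of targeted SNP panels (~1500 loci across
    the autosomes and X) at chromosome-arm resolution. Provides a
    closed-form allelic model linking arm genotype states and tumor purity
    to expected B-allele frequency and relative coverage, inverse
    estimators for purity and ploidy, a per-arm genotype caller with
    self-normalized coverage, sample-level classification into four
    chromosomal-alteration patterns including near-haploid and
    near-homozygous genome detection and genome-doubling inference, a
    forward read-count simulator for validation, and cohort-level summary
    statistics.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
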