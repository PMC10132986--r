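Package: tumortime
Title: Molecular Timing of Somatic Driver Events in Tumor Cohorts
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Infers when somatic driver events occurred during tumor
    development from bulk sequencing of primary tumors. Mutations are
    annotated with multiplicity and cancer-cell-fraction posteriors from
    read counts, purity and allelic copy number; chromosomal gains and
    whole-genome doubling are placed on a molecular time scale (pi) from
    multiplicity-stratified mutation counts; per-tumor timings are combined
    across a cohort into a consensus relative ordering (league model) with
    two-way p values for between-cohort timing differences; relative times
    are converted to years before diagnosis with a CpG>T clock-like
    mutational signature, including a Poisson-like model for the annual
    conversion of whole-genome doubled (tetraploid) tumors to triploid
    profiles. Intratumor heterogeneity metrics (MATH, fraction of genome
    altered, aneuploidy class) and a synthetic-cohort generator with full
    ground truth are included for validation.
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
    vcfR
Config/testthat/edition: 3
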