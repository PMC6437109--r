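Package: fcgrhap
Title: Copy-Number-Aware Haplotype Analysis of the FCGR2/3 Locus
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Haplotype-level genetic analysis of the segmentally duplicated
    FCGR2/3 locus (FCGR2A, FCGR3A, FCGR2C, FCGR3B, FCGR2B) from MLPA-style
    dosage data. Provides interpretation of probe ratios into copy-number and
    allele-dosage calls (including resolution of the FCGR2C Stop, classic-ORF
    and nonclassic-ORF haplotypes and FCGR2B/FCGR2C promoter allocation),
    copy-number-aware allele frequencies, EM haplotype-frequency estimation
    and pairwise linkage disequilibrium in CNV-free individuals, a
    CNV-stratified LD procedure, case-control association by Fisher exact
    tests and additive logistic regression, Mendelian phasing of
    parent-offspring trios with a transmission disequilibrium test, and
    fixed-effect inverse-variance meta-analysis combining case-control and
    TDT odds ratios. A synthetic-data generator produces haplotype pools with
    requested allele frequencies and pairwise r2, diploid populations,
    case-control samples under an additive disease model, ascertained trios,
    and noisy probe-ratio tables.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    metafor
Config/testthat/edition: 3
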