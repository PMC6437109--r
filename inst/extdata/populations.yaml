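# Default chromosome-pool parameters for the three reference populations.
#
# `marginals` are chromosome-level allele frequencies of the CNV-free
# component of the pool (the conditioning under which pairwise LD is defined
# at a CNV locus).  FCGR2C uses the internal four-haplotype model:
# Stop1 = stop codon + intact splice site, Stop2 = stop codon + splice-site
# mutant, ORF = classic open reading frame, NCORF = nonclassic ORF
# (ORF + splice-site mutant).  Stop1/Stop2 are collapsed to "Stop" in all
# reported output.
#
# `ld_targets` rows are [variant1, allele1, variant2, allele2, r2] with
# positive association between the two named alleles (allele-vs-rest
# collapse).
#
# `cnr_chrom_freqs` are per-chromosome CNR copy frequencies (0 = deletion,
# 1 = baseline, 2 = duplication).  European values come from parental
# chromosomes of the trio cohort; the other populations are moment fits to
# individual-level copy-number distributions (p0 = P0 + P1/2,
# p2 = P4 + P3/2), which preserve the mean copy number.
#
# `nc_orf_dup_attach` is the probability that the extra FCGR2C copy on a
# CNR1-duplicated chromosome carries the nonclassic ORF haplotype (encoding
# the strong association between increased CNR1 copy number and the
# nonclassic ORF).
EUR:
  marginals:
    FCGR2A_H131R: {H: 0.54, R: 0.46}
    FCGR2A_Q27W: {Q: 0.88, W: 0.12}
    FCGR3A_V158F: {V: 0.36, F: 0.64}
    FCGR2C_HAP: {Stop1: 0.82, Stop2: 0.02, ORF: 0.11, NCORF: 0.05}
    FCGR2C_PROM: {2B.1: 0.89, 2B.2: 0.11, 2B.4: 0.00}
    FCGR3B_HNA: {NA1: 0.35, NA2: 0.62, SH: 0.03}
    FCGR2B_PROM: {2B.1: 0.90, 2B.4: 0.10, 2B.2: 0.00}
    FCGR2B_I232T: {I: 0.88, T: 0.12}
  ld_targets:
    - [FCGR2C_HAP, ORF, FCGR2C_PROM, 2B.2, 0.92]
    - [FCGR2C_HAP, ORF, FCGR2A_Q27W, W, 0.63]
    - [FCGR2C_HAP, ORF, FCGR2B_PROM, 2B.4, 0.40]
    - [FCGR2C_HAP, ORF, FCGR3A_V158F, V, 0.24]
    - [FCGR2C_HAP, ORF, FCGR2A_H131R, H, 0.08]
    - [FCGR3A_V158F, V, FCGR2A_H131R, H, 0.06]
  cnr_chrom_freqs:
    CNR1: {0: 0.049, 1: 0.877, 2: 0.074}
    CNR2: {0: 0.006, 1: 0.976, 2: 0.018}
    CNR3: {0: 0.000, 1: 0.999, 2: 0.001}
  nc_orf_dup_attach: 0.5
CHN:
  marginals:
    FCGR2A_H131R: {H: 0.67, R: 0.33}
    FCGR2A_Q27W: {Q: 1.00, W: 0.00}
    FCGR3A_V158F: {V: 0.36, F: 0.64}
    # classic ORF present on 2 chromosomes out of 2 x 428 individuals
    FCGR2C_HAP: {Stop1: 0.9857, Stop2: 0.012, ORF: 0.0023, NCORF: 0.00}
    FCGR2C_PROM: {2B.1: 1.00, 2B.2: 0.00, 2B.4: 0.00}
    FCGR3B_HNA: {NA1: 0.62, NA2: 0.38, SH: 0.00}
    FCGR2B_PROM: {2B.1: 1.00, 2B.4: 0.00, 2B.2: 0.00}
    FCGR2B_I232T: {I: 0.74, T: 0.26}
  ld_targets: []
  cnr_chrom_freqs:
    CNR1: {0: 0.045, 1: 0.860, 2: 0.095}
    CNR2: {0: 0.005, 1: 0.975, 2: 0.020}
    CNR3: {0: 0.000, 1: 0.990, 2: 0.010}
  nc_orf_dup_attach: 0.0
AFR:
  marginals:
    FCGR2A_H131R: {H: 0.44, R: 0.56}
    FCGR2A_Q27W: {Q: 0.89, W: 0.11}
    FCGR3A_V158F: {V: 0.36, F: 0.64}
    FCGR2C_HAP: {Stop1: 0.88, Stop2: 0.02, ORF: 0.02, NCORF: 0.08}
    FCGR2C_PROM: {2B.1: 0.95, 2B.2: 0.05, 2B.4: 0.00}
    FCGR3B_HNA: {NA1: 0.38, NA2: 0.47, SH: 0.15}
    FCGR2B_PROM: {2B.1: 0.99, 2B.4: 0.01, 2B.2: 0.00}
    FCGR2B_I232T: {I: 0.73, T: 0.27}
  ld_targets:
    - [FCGR2C_HAP, ORF, FCGR2A_Q27W, W, 0.17]
  cnr_chrom_freqs:
    CNR1: {0: 0.055, 1: 0.860, 2: 0.085}
    CNR2: {0: 0.005, 1: 0.980, 2: 0.015}
    CNR3: {0: 0.001, 1: 0.998, 2: 0.001}
  nc_orf_dup_attach: 0.5
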