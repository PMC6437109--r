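# Default definition of the FCGR2/3 locus at 1q23.3.
# Genes are listed in physical order; coordinates are intentionally absent --
# the locus is modelled abstractly as genes, CNV regions and variant systems.
# CNR4 (rare) is merged into CNR1.
genes: [FCGR2A, FCGR3A, FCGR2C, FCGR3B, FCGR2B]
cnrs:
  CNR1:
    genes: [FCGR3B, FCGR2C]
    copy_range: [0, 4]
  CNR2:
    genes: [FCGR3A, FCGR2C]
    copy_range: [1, 4]
  CNR3:
    genes: [FCGR3A, FCGR2C]
    copy_range: [1, 3]
variants:
  FCGR2A_H131R:
    gene: FCGR2A
    alleles: [H, R]
  FCGR2A_Q27W:
    gene: FCGR2A
    alleles: [Q, W]
  FCGR3A_V158F:
    gene: FCGR3A
    alleles: [V, F]
  FCGR2C_HAP:
    gene: FCGR2C
    alleles: [Stop, ORF, NCORF]
  FCGR2C_PROM:
    gene: FCGR2C
    alleles: [2B.1, 2B.2, 2B.4]
  FCGR3B_HNA:
    gene: FCGR3B
    alleles: [NA1, NA2, SH]
  FCGR2B_PROM:
    gene: FCGR2B
    alleles: [2B.1, 2B.4, 2B.2]
  FCGR2B_I232T:
    gene: FCGR2B
    alleles: [I, T]
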