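test_that("allele frequencies use gene-copy denominators", {
  # one individual with a duplicated CNR1 carrying three Stop copies
  g <- combine_chromosomes(
    chrom_haplotype(c(CNR1 = 2), alleles = list(
      FCGR2A_H131R = "H", FCGR2A_Q27W = "Q", FCGR3A_V158F = "F",
      FCGR2C_HAP = c("Stop", "Stop"), FCGR2C_PROM = c("2B.1", "2B.1"),
      FCGR3B_HNA = c("NA1", "NA2"), FCGR2B_PROM = "2B.1",
      FCGR2B_I232T = "I")),
    chrom_haplotype(alleles = list(
      FCGR2A_H131R = "H", FCGR2A_Q27W = "Q", FCGR3A_V158F = "F",
      FCGR2C_HAP = "Stop", FCGR2C_PROM = "2B.1", FCGR3B_HNA = "NA2",
      FCGR2B_PROM = "2B.1", FCGR2B_I232T = "I")))
  fr <- allele_frequency(g, "FCGR2C_HAP")
  expect_equal(fr$total[1], 3)
  expect_equal(fr$frequency[fr$allele == "Stop"], 1)

  # monomorphic sample: alternate allele frequency 0
  pool <- toy_pool(list(FCGR2A_H131R = c(H = 1)))
  gg <- sample_population(pool, 10, seed = 1)
  fr2 <- allele_frequency(gg, "FCGR2A_H131R")
  expect_equal(fr2$frequency[fr2$allele == "R"], 0)

  # summary-count path: the published case ORF cell, 131/836
  fr3 <- allele_frequency_counts(c(ORF = 131, Stop = 679, NCORF = 26), 836,
                                 "FCGR2C_HAP")
  expect_equal(fr3$frequency[fr3$allele == "ORF"], 131 / 836)
  expect_equal(round(100 * fr3$frequency[fr3$allele == "ORF"], 1), 15.7)
  expect_error(allele_frequency_counts(c(A = 3, B = 2), 6), "sum")
})

test_that("frequencies within a variant always sum to one", {
  g <- sample_population(eur_pool(), 400, seed = 31)
  for (v in c("FCGR2C_HAP", "FCGR3B_HNA", "FCGR3A_V158F")) {
    fr <- allele_frequency(g, v)
    expect_equal(sum(fr$frequency), 1, tolerance = 1e-12)
    expect_equal(sum(fr$count), fr$total[1])
  }
})

cnv_free <- function(g) g[g$CNR1 == 2 & g$CNR2 == 2 & g$CNR3 == 2, ]

test_that("EM equals direct counting when phase is unambiguous", {
  pool <- toy_pool(list(FCGR2A_H131R = c(H = 0.5, R = 0.5),
                        FCGR2B_I232T = c(I = 0.5, T = 0.5)))
  g <- sample_population(pool, 60, seed = 41)
  hom <- g[(g$FCGR2A_H %% 2 == 0) & (g$FCGR2B_I %% 2 == 0), ]
  em <- em_haplotypes(hom, c("FCGR2A_H131R", "FCGR2B_I232T"))
  # homozygous-only data: haplotype frequency = direct count share
  for (i in seq_len(nrow(em))) {
    cnt <- sum(hom$FCGR2A_H == ifelse(em$FCGR2A_H131R[i] == "H", 2, 0) &
                 hom$FCGR2B_I == ifelse(em$FCGR2B_I232T[i] == "I", 2, 0))
    expect_equal(em$freq[i], cnt / nrow(hom), tolerance = 1e-9)
  }
})

test_that("EM matches the independent maximum-likelihood oracle", {
  set.seed(7)
  pool <- toy_pool(list(FCGR2A_H131R = c(H = 0.6, R = 0.4),
                        FCGR2B_I232T = c(I = 0.7, T = 0.3)),
                   ld_targets = list(c("FCGR2A_H131R", "H",
                                       "FCGR2B_I232T", "T", 0.2)))
  for (rep in 1:6) {
    g <- sample_population(pool, sample(3:6, 1), seed = 500 + rep)
    em <- em_haplotypes(g, c("FCGR2A_H131R", "FCGR2B_I232T"))
    bf <- brute_force_ml(g, c("FCGR2A_H131R", "FCGR2B_I232T"))
    ll_em <- tail(attr(em, "loglik"), 1)
    # the two optima must coincide in likelihood; tiny double-het datasets
    # can have label-symmetric global maxima, so frequencies are compared
    # through their (optimum-invariant) marginals
    expect_gte(ll_em, attr(bf, "loglik") - 1e-6)
    expect_lt(abs(ll_em - attr(bf, "loglik")), 1e-4)
    for (v in c("FCGR2A_H131R", "FCGR2B_I232T")) {
      m_em <- tapply(em$freq, em[[v]], sum)
      m_bf <- tapply(bf$freq, bf[[v]], sum)
      expect_equal(as.numeric(m_em[names(m_bf)]), as.numeric(m_bf),
                   tolerance = 1e-3)
    }
  }
})

test_that("EM log-likelihood is non-decreasing and rejects CNV individuals", {
  g <- cnv_free(sample_population(eur_pool(), 300, seed = 51))
  em <- em_haplotypes(g, c("FCGR2C_HAP", "FCGR2A_Q27W"))
  ll <- attr(em, "loglik")
  expect_true(all(diff(ll) >= -1e-8))
  expect_equal(sum(em$freq), 1, tolerance = 1e-9)

  g_cnv <- sample_population(eur_pool(), 200, seed = 52)
  g_cnv <- g_cnv[g_cnv$CNR1 != 2, ]
  expect_error(em_haplotypes(g_cnv, c("FCGR2C_HAP", "FCGR2A_Q27W")),
               "CNV-free")
})

test_that("LD statistics follow the closed forms", {
  mk <- function(pA, pB, pAB) {
    data.frame(FCGR2A_H131R = c("H", "H", "R", "R"),
               FCGR2B_I232T = c("I", "T", "I", "T"),
               freq = c(pAB, pA - pAB, pB - pAB, 1 - pA - pB + pAB))
  }
  eq <- ld_from_haplotypes(mk(0.3, 0.4, 0.12), "FCGR2A_H131R",
                           "FCGR2B_I232T", "H", "I")
  expect_equal(eq$r2, 0)
  expect_equal(eq$dprime, 0)

  perfect <- ld_from_haplotypes(mk(0.5, 0.5, 0.5), "FCGR2A_H131R",
                                "FCGR2B_I232T", "H", "I")
  expect_equal(perfect$r2, 1)
  expect_equal(perfect$dprime, 1)

  # near-complete LD between two rare alleles (the ORF ~ 2B.2 pattern)
  x <- ld_from_haplotypes(mk(0.11, 0.115, 0.1086), "FCGR2A_H131R",
                          "FCGR2B_I232T", "H", "I", n = 1500)
  D <- 0.1086 - 0.11 * 0.115
  expect_equal(x$r2, D^2 / (0.11 * 0.89 * 0.115 * 0.885), tolerance = 1e-12)
  expect_equal(round(x$r2, 2), 0.92)
  expect_lt(x$p, 1e-10)

  expect_error(ld_from_haplotypes(mk(0, 0.4, 0), "FCGR2A_H131R",
                                  "FCGR2B_I232T", "H", "I"), "monomorphic")
})

test_that("r2 <= D' <= 1 and allele-label swap invariance", {
  set.seed(11)
  for (i in 1:50) {
    pA <- runif(1, 0.05, 0.95); pB <- runif(1, 0.05, 0.95)
    lo <- max(0, pA + pB - 1); hi <- min(pA, pB)
    pAB <- runif(1, lo, hi)
    tab <- data.frame(v1 = c("A", "A", "a", "a"), v2 = c("B", "b", "B", "b"),
                      freq = c(pAB, pA - pAB, pB - pAB, 1 - pA - pB + pAB))
    x <- ld_from_haplotypes(tab, "v1", "v2", "A", "B")
    expect_gte(x$dprime, x$r2 - 1e-12)
    expect_lte(x$dprime, 1 + 1e-12)
    expect_gte(x$r2, -1e-12)
    # swapping focal alleles leaves r2 and D' unchanged
    y <- ld_from_haplotypes(tab, "v1", "v2", "a", "b")
    expect_equal(x$r2, y$r2, tolerance = 1e-12)
    expect_equal(x$dprime, y$dprime, tolerance = 1e-12)
  }
})

test_that("EM recovers pool r2 within 0.05 at n = 2000", {
  # recovery check at the strongest reported pairing
  pool <- eur_pool()
  g <- cnv_free(sample_population(pool, 2600, seed = 61))
  em <- em_haplotypes(g, c("FCGR2C_HAP", "FCGR2A_Q27W"))
  x <- ld_from_haplotypes(em, "FCGR2C_HAP", "FCGR2A_Q27W", "ORF", "W")
  expect_lt(abs(x$r2 - 0.63), 0.05)
})

test_that("CNV-stratified LD detects duplication-linked alleles", {
  # balanced table: identical frequencies across strata
  g1 <- rbind(
    combine_chromosomes(chrom_haplotype(alleles = list(
      FCGR2A_H131R = "H", FCGR2A_Q27W = "Q", FCGR3A_V158F = "F",
      FCGR2C_HAP = "Stop", FCGR2C_PROM = "2B.1", FCGR3B_HNA = "NA1",
      FCGR2B_PROM = "2B.1", FCGR2B_I232T = "I")),
      chrom_haplotype(alleles = list(
        FCGR2A_H131R = "H", FCGR2A_Q27W = "Q", FCGR3A_V158F = "F",
        FCGR2C_HAP = "Stop", FCGR2C_PROM = "2B.1", FCGR3B_HNA = "NA2",
        FCGR2B_PROM = "2B.1", FCGR2B_I232T = "I")))
  )
  g1$individual_id <- "i1"
  del <- combine_chromosomes(
    chrom_haplotype(c(CNR1 = 0), alleles = list(
      FCGR2A_H131R = "H", FCGR2A_Q27W = "Q", FCGR3A_V158F = "F",
      FCGR2C_HAP = character(0), FCGR2C_PROM = character(0),
      FCGR3B_HNA = character(0), FCGR2B_PROM = "2B.1", FCGR2B_I232T = "I")),
    chrom_haplotype(alleles = list(
      FCGR2A_H131R = "H", FCGR2A_Q27W = "Q", FCGR3A_V158F = "F",
      FCGR2C_HAP = "Stop", FCGR2C_PROM = "2B.1", FCGR3B_HNA = "NA1",
      FCGR2B_PROM = "2B.1", FCGR2B_I232T = "I")), id = "i2")
  both <- rbind(g1, del)
  res <- cnv_stratified_ld(both, "CNR1", "FCGR3B_HNA")
  expect_equal(res$p, 1)

  # nonclassic ORF exclusively on duplicated CNR1 chromosomes
  pool <- eur_pool()
  g <- sample_population(pool, 900, seed = 71)
  out <- cnv_stratified_ld(g, "CNR1", "FCGR2C_HAP")
  expect_lt(out$p, 0.001)
  expect_true(out$method %in% c("exact", "monte-carlo"))

  g_one <- g[g$CNR1 == 2, ]
  expect_error(cnv_stratified_ld(g_one, "CNR1", "FCGR2C_HAP"), "stratum")
})
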