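test_that("Fisher genotype test handles r x 2 tables", {
  # identical proportions: no evidence against independence
  expect_equal(as.numeric(fisher_genotype_test(c(10, 10), c(20, 20))), 1)
  p <- fisher_genotype_test(c(30, 10), c(10, 30))
  expect_lt(as.numeric(p), 0.001)
  expect_equal(attr(p, "method"), "exact")
  pm <- fisher_genotype_test(c(30, 10), c(10, 30), simulate = TRUE, B = 1e5,
                             seed = 2)
  expect_equal(attr(pm, "method"), "monte-carlo")
  expect_lt(abs(as.numeric(pm) - as.numeric(p)), 0.005)
  expect_error(fisher_genotype_test(c(10), c(10)), "categories")
})

test_that("additive logistic regression estimates the per-copy OR", {
  # equal dose distributions: OR ~ 1, p ~ 1
  r <- additive_logistic_counts(0:2, c(50, 30, 10), c(100, 60, 20), "null")
  expect_equal(r$or, 1, tolerance = 1e-6)
  expect_gt(r$p, 0.99)
  expect_true(r$ci_lo <= r$or && r$or <= r$ci_hi)

  expect_error(additive_logistic(rep(1L, 10), rep(1L, 10)), "outcome")
  expect_error(additive_logistic(rep(1L, 10), rep(0:1, 5)), "monomorphic")
  expect_error(additive_logistic(c(0.5, 1), c(0, 1)), "integers")
  # perfect separation is diagnosed
  expect_error(additive_logistic(c(rep(0L, 20), rep(2L, 20)),
                                 c(rep(0L, 20), rep(1L, 20))),
               "separation")
})

test_that("additive OR approaches the allele cross-product ratio under HWE", {
  set.seed(19)
  p_case <- 0.30; p_ctrl <- 0.25; n <- 60000
  d_case <- stats::rbinom(n, 2, p_case)
  d_ctrl <- stats::rbinom(n, 2, p_ctrl)
  r <- additive_logistic(c(d_case, d_ctrl), c(rep(1, n), rep(0, n)))
  cross <- (sum(d_case) * (2 * n - sum(d_ctrl))) /
    ((2 * n - sum(d_case)) * sum(d_ctrl))
  expect_equal(r$or, cross, tolerance = 0.02)
})

test_that("additive-model type-I error is calibrated under the null", {
  set.seed(23)
  rej <- 0L; reps <- 1000L
  for (i in seq_len(reps)) {
    dose <- stats::rbinom(1000, 2, 0.3)
    status <- rep(0:1, each = 500)
    r <- additive_logistic(dose, status)
    if (r$p < 0.05) rej <- rej + 1L
  }
  # the exact Wald rejection rate at this design is ~0.045 (slightly
  # conservative); the band covers it plus Monte-Carlo noise at 1000 reps
  expect_lt(abs(rej / reps - 0.05), 0.025)
})

test_that("joint regression drops collinear columns and matches single fits", {
  set.seed(29)
  n <- 800
  x1 <- stats::rbinom(n, 2, 0.3)
  status <- stats::rbinom(n, 1, stats::plogis(-0.5 + 0.4 * x1))
  X <- cbind(a = x1, b = stats::rbinom(n, 2, 0.2), dupe = x1)
  res <- multiple_logistic(X, status)
  expect_setequal(res$variant, c("a", "b"))
  expect_match(attr(res, "dropped"), "dupe")

  single <- additive_logistic(x1, status, "a")
  only <- multiple_logistic(cbind(a = x1), status)
  expect_equal(only$or, single$or, tolerance = 1e-9)
  expect_equal(only$se, single$se, tolerance = 1e-9)
})

test_that("backward selection keeps true signals and empties null models", {
  set.seed(31)
  n <- 1200
  null_X <- cbind(a = stats::rbinom(n, 2, 0.3), b = stats::rbinom(n, 2, 0.4))
  status0 <- rep(0:1, each = n / 2)
  r0 <- backward_selection(null_X, sample(status0))
  expect_lte(nrow(r0), 1)  # occasionally one false positive at alpha 0.05

  x <- stats::rbinom(n, 2, 0.3)
  status <- stats::rbinom(n, 1, stats::plogis(-0.8 + 0.6 * x))
  r1 <- backward_selection(cbind(sig = x), status)
  expect_equal(r1$variant, "sig")

  # one true signal among LD-correlated nulls: the signal survives in most
  # replicates
  kept <- 0L
  for (s in 1:10) {
    set.seed(400 + s)
    z <- stats::rbinom(n, 2, 0.3)
    # correlated companion: copies z with flip noise
    flip <- stats::rbinom(n, 1, 0.2)
    comp <- pmin(2, pmax(0, z + ifelse(flip == 1, sample(c(-1, 1), n, TRUE), 0)))
    st <- stats::rbinom(n, 1, stats::plogis(-0.8 + 0.5 * z))
    rr <- backward_selection(cbind(signal = z, companion = comp), st)
    if ("signal" %in% rr$variant) kept <- kept + 1L
  }
  expect_gte(kept, 8L)
})

test_that("ORF association is independent of H131R on locus-realistic data", {
  pool <- eur_pool()
  m <- disease_model(log_or = c(FCGR2C_ORF = log(1.5)), prevalence = 0.01)
  cc <- sample_case_control(pool, m, 800, 1600, seed = 37)
  status <- c(rep(1, 800), rep(0, 1600))
  X <- cbind(FCGR2C_ORF = c(cc$cases$FCGR2C_ORF, cc$controls$FCGR2C_ORF),
             FCGR2A_H = c(cc$cases$FCGR2A_H, cc$controls$FCGR2A_H))
  res <- multiple_logistic(X, status)
  p_orf <- res$p[res$variant == "FCGR2C_ORF"]
  p_h <- res$p[res$variant == "FCGR2A_H"]
  expect_lt(p_orf, 0.05)
  expect_gt(p_h, p_orf)
})

test_that("the published summary analysis reproduces its own arithmetic", {
  res <- kd_case_control_analysis()
  orf <- res[res$variant == "FCGR2C_ORF", ]
  expect_equal(orf$freq_cases, 100 * 131 / 836, tolerance = 1e-12)
  expect_equal(orf$freq_controls, 100 * 213 / 1907, tolerance = 1e-12)
  # ORF + NC-ORF + Stop frequencies close over the same denominator
  nc <- res[res$variant == "FCGR2C_NCORF", ]
  stop_ca <- 100 - orf$freq_cases - nc$freq_cases
  expect_equal(round(stop_ca, 1), 81.2)
})
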