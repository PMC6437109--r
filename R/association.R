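# Case-control association: exact tests on genotype tables, additive
# logistic regression, joint models with collinearity handling, and
# backward selection.

#' Fisher exact test on a genotype-category table
#'
#' @param case_counts,control_counts non-negative integer counts over the
#'   same >= 2 genotype categories.
#' @param simulate use a seeded Monte-Carlo p-value (recorded in the
#'   \code{method} attribute) instead of the exact network algorithm.
#' @param B Monte-Carlo draws.
#' @param seed seed for the Monte-Carlo p-value.
#' @return p-value with attribute \code{method}.
#' @export
fisher_genotype_test <- function(case_counts, control_counts,
                                 simulate = FALSE, B = 1e6, seed = 1) {
  if (length(case_counts) < 2L || length(case_counts) != length(control_counts))
    stop("need counts over the same >= 2 genotype categories")
  tab <- cbind(cases = case_counts, controls = control_counts)
  if (any(tab < 0) || sum(tab) == 0) stop("invalid genotype table")
  tab <- tab[rowSums(tab) > 0, , drop = FALSE]
  if (simulate) {
    set.seed(seed)
    p <- stats::fisher.test(tab, simulate.p.value = TRUE, B = B)$p.value
    method <- "monte-carlo"
  } else {
    p <- stats::fisher.test(tab, workspace = 2e7)$p.value
    method <- "exact"
  }
  structure(p, method = method)
}

#' Additive logistic regression for one variant
#'
#' Maximum-likelihood logistic fit of case status on per-individual allele
#' copy count (dose). OR = exp(slope) with Wald 95\% CI and p-value. Dose 3
#' (possible at duplicated genes) is kept as its own level of the additive
#' coding.
#'
#' @param dose integer vector of allele copy counts.
#' @param status 0/1 (or logical) case status.
#' @param variant label for the output.
#' @return one-row data frame of class \code{association_result}: variant,
#'   or, ci_lo, ci_hi, p, log_or, se, model.
#' @export
additive_logistic <- function(dose, status, variant = NA_character_) {
  status <- as.integer(status)
  if (any(dose < 0) || any(dose != round(dose)))
    stop("doses must be non-negative integers")
  if (length(unique(status)) < 2L) stop("both outcome classes required")
  if (length(unique(dose)) < 2L)
    stop("monomorphic dose for ", variant, ": OR undefined")
  fit <- suppressWarnings(stats::glm(status ~ dose, family = stats::binomial,
                                     control = list(epsilon = 1e-10,
                                                    maxit = 100)))
  co <- stats::coef(summary(fit))["dose", ]
  if (!fit$converged || abs(co[1]) > 15)
    stop("logistic fit for ", variant,
         " did not converge (possible perfect separation)")
  assoc_row(variant, co[1], co[2], model = "single")
}

assoc_row <- function(variant, log_or, se, model) {
  z <- stats::qnorm(0.975)
  out <- data.frame(variant = variant, or = exp(log_or),
                    ci_lo = exp(log_or - z * se),
                    ci_hi = exp(log_or + z * se),
                    p = 2 * stats::pnorm(-abs(log_or / se)),
                    log_or = unname(log_or), se = unname(se),
                    model = model, stringsAsFactors = FALSE)
  class(out) <- c("association_result", "data.frame")
  rownames(out) <- NULL
  out
}

#' Additive logistic regression from dose-count summaries
#'
#' Expands per-dose case/control counts (as printed in a genotype table)
#' into individual records and fits \code{\link{additive_logistic}}.
#'
#' @param doses dose levels.
#' @param case_counts,control_counts individuals per dose level.
#' @param variant label.
#' @return an \code{association_result} row.
#' @export
additive_logistic_counts <- function(doses, case_counts, control_counts,
                                     variant = NA_character_) {
  dose <- c(rep(doses, case_counts), rep(doses, control_counts))
  status <- c(rep(1L, sum(case_counts)), rep(0L, sum(control_counts)))
  additive_logistic(dose, status, variant)
}

#' Joint (multiple) logistic regression over several variants
#'
#' Fits case status on all dose columns jointly. Columns whose pairwise
#' dose correlation with an earlier column exceeds \code{drop_threshold}
#' are dropped before fitting (the later column loses), with the reason
#' recorded in \code{attr(, "dropped")}.
#'
#' @param doses numeric matrix or data frame, one column per variant.
#' @param status 0/1 case status.
#' @param drop_threshold absolute pairwise correlation above which the
#'   later column is dropped.
#' @return \code{association_result} rows (model = "multiple"), with
#'   attribute \code{dropped}.
#' @export
multiple_logistic <- function(doses, status, drop_threshold = 0.95) {
  X <- as.matrix(doses)
  status <- as.integer(status)
  if (length(unique(status)) < 2L) stop("both outcome classes required")
  dropped <- character(0)
  keep <- rep(TRUE, ncol(X))
  if (ncol(X) > 1L) {
    cm <- suppressWarnings(stats::cor(X))
    for (j in 2:ncol(X)) {
      earlier <- which(keep[seq_len(j - 1)])
      if (any(abs(cm[j, earlier]) > drop_threshold, na.rm = TRUE)) {
        keep[j] <- FALSE
        partner <- earlier[which.max(abs(cm[j, earlier]))]
        dropped <- c(dropped, sprintf(
          "%s (|cor| = %.3f with %s)", colnames(X)[j],
          max(abs(cm[j, earlier])), colnames(X)[partner]))
      }
    }
  }
  Xk <- X[, keep, drop = FALSE]
  if (qr(cbind(1, Xk))$rank < ncol(Xk) + 1L)
    stop("design matrix rank deficient after drops; offending columns: ",
         paste(colnames(Xk), collapse = ", "))
  df <- data.frame(status = status, Xk, check.names = FALSE)
  fit <- suppressWarnings(stats::glm(status ~ ., data = df,
                                     family = stats::binomial,
                                     control = list(epsilon = 1e-10,
                                                    maxit = 100)))
  cs <- stats::coef(summary(fit))
  rows <- do.call(rbind, lapply(colnames(Xk), function(v) {
    nm <- if (v %in% rownames(cs)) v else paste0("`", v, "`")
    assoc_row(v, cs[nm, 1], cs[nm, 2], model = "multiple")
  }))
  attr(rows, "dropped") <- dropped
  rows
}

#' Backward selection over a joint logistic model
#'
#' Iteratively removes the variant with the highest Wald p-value until every
#' remaining variant has p < alpha. Ties break by column order. May return
#' an empty model.
#'
#' @param doses dose matrix or data frame.
#' @param status 0/1 case status.
#' @param alpha retention threshold.
#' @param drop_threshold collinearity threshold (applied once, up front).
#' @return \code{association_result} rows (model = "backward") for the
#'   retained variants; attribute \code{removed} records the removal order.
#' @export
backward_selection <- function(doses, status, alpha = 0.05,
                               drop_threshold = 0.95) {
  X <- as.matrix(doses)
  first <- multiple_logistic(X, status, drop_threshold)
  dropped <- attr(first, "dropped")
  current <- first$variant
  removed <- character(0)
  repeat {
    if (!length(current)) {
      res <- first[0, ]
      break
    }
    res <- multiple_logistic(X[, current, drop = FALSE], status,
                             drop_threshold = 1.1)
    if (all(res$p < alpha)) break
    worst <- current[which.max(res$p)]
    removed <- c(removed, worst)
    current <- setdiff(current, worst)
  }
  if (nrow(res)) res$model <- "backward"
  attr(res, "removed") <- removed
  attr(res, "dropped") <- dropped
  res
}

#' Published Kawasaki-disease case-control summary counts
#'
#' Genotype-category counts and CNR copy-number distributions for the
#' European case-control comparison (405 cases, 919 controls), transcribed
#' from the published summary table. These printed counts are the input for
#' the desk-scale reproduction of the allele frequencies, Fisher tests and
#' additive odds ratios.
#'
#' @return nested list with \code{cnr} (per-group copy-number counts) and
#'   \code{variants} (per-variant dose levels and case/control counts).
#' @export
kd_case_control_counts <- function() {
  list(
    n = c(cases = 405, controls = 919),
    cnr = list(
      CNR1 = list(copies = 0:4, cases = c(1, 27, 348, 27, 2),
                  controls = c(1, 60, 768, 83, 7)),
      CNR2 = list(copies = 1:4, cases = c(3, 376, 25, 1),
                  controls = c(11, 866, 41, 1)),
      CNR3 = list(copies = 2:3, cases = c(405, 0), controls = c(917, 2))
    ),
    variants = list(
      FCGR2A_Q27W = list(gene = "FCGR2A", allele = "W", doses = 0:2,
                         cases = c(289, 108, 8), controls = c(713, 194, 12)),
      FCGR2A_H131R = list(gene = "FCGR2A", allele = "H", doses = 0:2,
                          cases = c(72, 211, 122), controls = c(187, 463, 269)),
      FCGR3A_V158F = list(gene = "FCGR3A", allele = "V", doses = 0:3,
                          cases = c(150, 205, 47, 3),
                          controls = c(386, 403, 128, 2)),
      FCGR2C_PROM_2B2 = list(gene = "FCGR2C", allele = "2B.2", doses = 0:3,
                             cases = c(286, 110, 9, 0),
                             controls = c(717, 185, 16, 1)),
      FCGR2C_ORF = list(gene = "FCGR2C", allele = "ORF", doses = 0:3,
                        cases = c(283, 113, 9, 0),
                        controls = c(721, 184, 13, 1)),
      FCGR2C_NCORF = list(gene = "FCGR2C", allele = "NCORF", doses = 0:2,
                          cases = c(389, 6, 10), controls = c(853, 33, 33)),
      FCGR3B_NA1 = list(gene = "FCGR3B", allele = "NA1", doses = 0:3,
                        cases = c(158, 201, 45, 1),
                        controls = c(373, 430, 114, 2)),
      FCGR2B_PROM_2B4 = list(gene = "FCGR2B", allele = "2B.4", doses = 0:2,
                             cases = c(307, 93, 5),
                             controls = c(748, 157, 14)),
      FCGR2B_I232T = list(gene = "FCGR2B", allele = "T", doses = 0:2,
                          cases = c(322, 76, 7), controls = c(697, 201, 21))
    )
  )
}

#' Gene-copy denominator from CNR copy-number counts
#'
#' Total gene copies in a group of n individuals:
#' 2n + sum over CNRs containing the gene of sum((copies - 2) x count).
#'
#' @param gene gene name.
#' @param n individuals in the group.
#' @param cnr_counts list per CNR with elements \code{copies} and a count
#'   vector for the group.
#' @param group name of the count vector ("cases" or "controls").
#' @param locus a \code{locus_definition}.
#' @return total gene copies.
#' @export
copy_denominator <- function(gene, n, cnr_counts,
                             group = c("cases", "controls"),
                             locus = default_locus()) {
  group <- match.arg(group)
  extra <- 0
  for (cnr in cnrs_containing(locus, gene)) {
    cc <- cnr_counts[[cnr]]
    if (is.null(cc)) next
    extra <- extra + sum((cc$copies - 2) * cc[[group]])
  }
  2 * n + extra
}

#' Desk-scale reproduction of the published case-control analysis
#'
#' From the printed genotype-category and CNR counts, recomputes per-variant
#' copy-number-aware allele frequencies (cases and controls), the Fisher
#' exact genotype-table p, and the additive logistic OR with Wald CI.
#'
#' @param counts output of \code{\link{kd_case_control_counts}}.
#' @param locus a \code{locus_definition}.
#' @return data frame, one row per tabulated variant allele.
#' @export
kd_case_control_analysis <- function(counts = kd_case_control_counts(),
                                     locus = default_locus()) {
  rows <- lapply(names(counts$variants), function(v) {
    vc <- counts$variants[[v]]
    denom_ca <- copy_denominator(vc$gene, counts$n[["cases"]], counts$cnr,
                                 "cases", locus)
    denom_co <- copy_denominator(vc$gene, counts$n[["controls"]], counts$cnr,
                                 "controls", locus)
    ac_ca <- sum(vc$doses * vc$cases)
    ac_co <- sum(vc$doses * vc$controls)
    fp <- fisher_genotype_test(vc$cases, vc$controls)
    lr <- additive_logistic_counts(vc$doses, vc$cases, vc$controls, v)
    data.frame(variant = v, allele = vc$allele,
               freq_cases = 100 * ac_ca / denom_ca,
               freq_controls = 100 * ac_co / denom_co,
               fisher_p = as.numeric(fp),
               or = lr$or, ci_lo = lr$ci_lo, ci_hi = lr$ci_hi,
               wald_p = lr$p, log_or = lr$log_or, se = lr$se,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
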