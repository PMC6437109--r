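# Fixed-effect inverse-variance meta-analysis combining case-control and
# TDT-derived odds ratios.

#' Effect estimate
#'
#' @param log_or log odds ratio.
#' @param se standard error of the log OR (> 0).
#' @param source tag, e.g. "case_control" or "tdt".
#' @return one-row data frame of class \code{effect_estimate}.
#' @export
effect_estimate <- function(log_or, se, source = "case_control") {
  if (!is.finite(se) || se <= 0) stop("SE must be finite and > 0")
  out <- data.frame(source = source, log_or = log_or, se = se,
                    stringsAsFactors = FALSE)
  class(out) <- c("effect_estimate", "data.frame")
  out
}

#' TDT counts to an odds-ratio effect
#'
#' Converts transmitted/untransmitted counts into a log odds ratio suitable
#' for inverse-variance pooling with a case-control estimate:
#' log OR = ln(T/U), SE = sqrt(1/T + 1/U).
#'
#' @param T,U transmitted and untransmitted counts (> 0 unless
#'   \code{correction}).
#' @param correction add 0.5 to both counts (only way to handle a zero
#'   count; off by default and recorded in the \code{correction} column).
#' @return an \code{effect_estimate} row (source "tdt").
#' @export
tdt_to_effect <- function(T, U, correction = FALSE) {
  if (!correction && (T <= 0 || U <= 0))
    stop("T and U must both be positive; use correction = TRUE to add 0.5 ",
         "to both counts")
  if (correction) { T <- T + 0.5; U <- U + 0.5 }
  out <- effect_estimate(log(T / U), sqrt(1 / T + 1 / U), source = "tdt")
  out$correction <- correction
  out
}

#' Effect estimate from an OR and its 95% CI
#'
#' Recovers the log-OR standard error from a symmetric-in-log Wald interval:
#' SE = (ln(upper) - ln(lower)) / (2 x 1.959964).
#'
#' @param or odds ratio.
#' @param lo,hi 95\% confidence bounds.
#' @param source tag.
#' @return an \code{effect_estimate} row.
#' @export
effect_from_or_ci <- function(or, lo, hi, source = "case_control") {
  effect_estimate(log(or), (log(hi) - log(lo)) / (2 * stats::qnorm(0.975)),
                  source = source)
}

#' Fixed-effect inverse-variance pooling
#'
#' weights proportional to 1/SE^2; pooled log OR is the weighted mean with
#' SE = 1/sqrt(sum of weights); Z and two-sided p follow.
#'
#' @param effects data frame of \code{effect_estimate} rows (or a list of
#'   them), normally two: a case-control and a TDT effect.
#' @param q also compute Cochran's Q heterogeneity statistic.
#' @return list of class \code{meta_result}: or, ci_lo, ci_hi, log_or, se,
#'   z, p, weights (normalized, by source), and optionally q/q_df/q_p.
#' @export
pool_effects <- function(effects, q = FALSE) {
  if (is.list(effects) && !is.data.frame(effects))
    effects <- do.call(rbind, effects)
  if (any(effects$se <= 0)) stop("all SEs must be > 0")
  if (nrow(effects) < 2L)
    warning("single effect supplied; returned unchanged")
  w <- 1 / effects$se^2
  log_or <- sum(w * effects$log_or) / sum(w)
  se <- 1 / sqrt(sum(w))
  z <- log_or / se
  zq <- stats::qnorm(0.975)
  out <- list(or = exp(log_or), ci_lo = exp(log_or - zq * se),
              ci_hi = exp(log_or + zq * se), log_or = log_or, se = se,
              z = z, p = 2 * stats::pnorm(-abs(z)),
              weights = stats::setNames(w / sum(w), effects$source))
  if (q) {
    out$q <- sum(w * (effects$log_or - log_or)^2)
    out$q_df <- nrow(effects) - 1L
    out$q_p <- stats::pchisq(out$q, out$q_df, lower.tail = FALSE)
  }
  structure(out, class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("<meta_result> pooled OR %.3f (95%% CI %.3f-%.3f), Z = %.3f, p = %.3g\n",
              x$or, x$ci_lo, x$ci_hi, x$z, x$p))
  cat("  weights:", paste(sprintf("%s %.1f%%", names(x$weights),
                                  100 * x$weights), collapse = ", "), "\n")
  invisible(x)
}
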