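# Population statistics: copy-number-aware allele frequencies, EM haplotype
# frequency estimation in CNV-free individuals, pairwise LD, and the
# CNV-stratified LD procedure.

#' Copy-number-aware allele frequency
#'
#' frequency(allele) = sum of allele dosages / sum of gene copy numbers. For
#' genes inside CNRs the denominator is the total number of gene copies in
#' the sample (not 2n), which is what makes frequencies of the three FCGR2C
#' haplotypes sum to 1 in the presence of CNV.
#'
#' @param genotypes genotype data frame.
#' @param variant variant id.
#' @param locus a \code{locus_definition}.
#' @return data frame of class \code{frequency_result}: variant, allele,
#'   count, total, frequency.
#' @export
allele_frequency <- function(genotypes, variant, locus = default_locus()) {
  validate_genotypes(genotypes, locus)
  counts <- colSums(genotypes[variant_columns(locus, variant)])
  total <- sum(gene_copy_number(genotypes, variant_gene(locus, variant),
                                locus))
  allele_frequency_counts(stats::setNames(as.numeric(counts),
                                          variant_alleles(locus, variant)),
                          total, variant)
}

#' Allele frequency from summary counts
#'
#' Same result as \code{\link{allele_frequency}} computed directly from
#' per-allele counts and a gene-copy denominator (e.g. expanded from a
#' published genotype-category table).
#'
#' @param counts named numeric vector of allele counts.
#' @param total total gene copies (denominator).
#' @param variant variant id used for labelling.
#' @return a \code{frequency_result} data frame.
#' @export
allele_frequency_counts <- function(counts, total, variant = NA_character_) {
  if (any(counts < 0) || total <= 0) stop("invalid counts")
  if (abs(sum(counts) - total) > 1e-9)
    stop("allele counts (", sum(counts), ") do not sum to the gene-copy ",
         "denominator (", total, ")")
  out <- data.frame(variant = variant, allele = names(counts),
                    count = as.numeric(counts), total = total,
                    frequency = as.numeric(counts) / total,
                    stringsAsFactors = FALSE)
  class(out) <- c("frequency_result", "data.frame")
  rownames(out) <- NULL
  out
}

# per-individual genotype at `variant` as a 2-allele pair (CNV-free only)
genotype_pairs <- function(genotypes, variant, locus) {
  cols <- variant_columns(locus, variant)
  alle <- variant_alleles(locus, variant)
  D <- as.matrix(genotypes[cols])
  t(apply(D, 1, function(d) rep(alle, d)[1:2]))
}

#' EM haplotype-frequency estimation in CNV-free individuals
#'
#' Expectation-maximization over unphased multilocus genotypes (gene-counting
#' algorithm). All individuals must carry exactly 2 copies of every involved
#' gene; callers must filter CNV individuals first. Initialization is the
#' product of marginal allele frequencies; on small problems (up to 64 hard
#' phase assignments of the genotype classes) every hard assignment also
#' seeds a deterministic restart and the best final likelihood wins, which
#' guards against the local modes tiny datasets can produce. Iteration
#' stops when the relative log-likelihood change falls below \code{tol} or
#' after \code{max_iter} iterations; the log-likelihood is non-decreasing
#' within each run.
#'
#' @param genotypes genotype data frame of CNV-free individuals.
#' @param variants character vector of >= 2 variant ids.
#' @param locus a \code{locus_definition}.
#' @param tol relative log-likelihood convergence tolerance.
#' @param max_iter iteration cap.
#' @return data frame with one column per variant (allele labels), a
#'   \code{freq} column summing to 1, and attributes \code{loglik}
#'   (trajectory) and \code{iterations}.
#' @export
em_haplotypes <- function(genotypes, variants, locus = default_locus(),
                          tol = 1e-8, max_iter = 1000) {
  validate_genotypes(genotypes, locus)
  for (v in variants) {
    cn <- gene_copy_number(genotypes, variant_gene(locus, v), locus)
    if (any(cn != 2L))
      stop("individual ", genotypes$individual_id[which(cn != 2L)[1]],
           " carries CNV at ", variant_gene(locus, v),
           "; EM requires CNV-free individuals (filter first)")
  }
  n <- nrow(genotypes)
  pairs <- lapply(variants, function(v) genotype_pairs(genotypes, v, locus))
  names(pairs) <- variants

  # haplotype space: cartesian product of observed alleles
  alle <- lapply(variants, function(v)
    sort(unique(as.vector(pairs[[v]]))))
  names(alle) <- variants
  haps <- expand.grid(alle, stringsAsFactors = FALSE)
  hap_key <- do.call(paste, c(haps, sep = "|"))

  # per-individual list of compatible (h1, h2) index pairs
  geno_key <- do.call(paste, c(lapply(variants, function(v)
    paste(pairs[[v]][, 1], pairs[[v]][, 2])), sep = "|"))
  expand_phase <- function(i) {
    per_var <- lapply(variants, function(v) {
      a <- pairs[[v]][i, ]
      if (a[1] == a[2]) list(a) else list(a, rev(a))
    })
    combos <- expand.grid(lapply(per_var, seq_along))
    ph <- unique(t(apply(combos, 1, function(ci) {
      h1 <- vapply(seq_along(variants), function(j) per_var[[j]][[ci[j]]][1],
                   character(1))
      h2 <- vapply(seq_along(variants), function(j) per_var[[j]][[ci[j]]][2],
                   character(1))
      k1 <- match(paste(h1, collapse = "|"), hap_key)
      k2 <- match(paste(h2, collapse = "|"), hap_key)
      sort(c(k1, k2))
    })))
    ph
  }
  uk <- unique(geno_key)
  phase_sets <- lapply(match(uk, geno_key), expand_phase)
  names(phase_sets) <- uk
  weights <- as.numeric(table(geno_key)[uk])

  loglik <- function(f) {
    sum(weights * log(vapply(phase_sets, function(ph) {
      sum(apply(ph, 1, function(hp)
        f[hp[1]] * f[hp[2]] * (2 - (hp[1] == hp[2]))))
    }, numeric(1))))
  }
  run_em <- function(f) {
    ll <- loglik(pmax(f, 1e-300))
    traj <- ll
    for (it in seq_len(max_iter)) {
      counts <- numeric(nrow(haps))
      for (g in seq_along(phase_sets)) {
        ph <- phase_sets[[g]]
        pw <- apply(ph, 1, function(hp)
          f[hp[1]] * f[hp[2]] * (2 - (hp[1] == hp[2])))
        pw <- pw / sum(pw)
        for (r in seq_len(nrow(ph))) {
          counts[ph[r, 1]] <- counts[ph[r, 1]] + weights[g] * pw[r]
          counts[ph[r, 2]] <- counts[ph[r, 2]] + weights[g] * pw[r]
        }
      }
      f_new <- counts / (2 * n)
      ll_new <- loglik(pmax(f_new, 1e-300))
      traj <- c(traj, ll_new)
      done <- abs(ll_new - ll) < tol * abs(ll)
      f <- f_new; ll <- ll_new
      if (done) break
    }
    list(f = f, traj = traj)
  }

  # primary start: product of marginals
  f0 <- rep(1, nrow(haps))
  for (v in variants) {
    m <- table(as.vector(pairs[[v]])) / (2 * n)
    f0 <- f0 * as.numeric(m[haps[[v]]])
  }
  starts <- list(f0 / sum(f0))
  # on tiny problems the likelihood can be multimodal and the symmetric
  # product start can settle on an inferior mode; add deterministic
  # restarts seeded from every hard phase assignment of the genotype
  # classes
  n_combo <- prod(vapply(phase_sets, nrow, numeric(1)))
  if (is.finite(n_combo) && n_combo > 1 && n_combo <= 64) {
    hard <- expand.grid(lapply(phase_sets, function(ph) seq_len(nrow(ph))))
    for (r in seq_len(nrow(hard))) {
      cnt <- numeric(nrow(haps))
      for (g in seq_along(phase_sets)) {
        hp <- phase_sets[[g]][hard[r, g], ]
        cnt[hp[1]] <- cnt[hp[1]] + weights[g]
        cnt[hp[2]] <- cnt[hp[2]] + weights[g]
      }
      f1 <- pmax(cnt / (2 * n), 1e-6)
      starts <- c(starts, list(f1 / sum(f1)))
    }
  }
  fits <- lapply(starts, run_em)
  best <- which.max(vapply(fits, function(x) x$traj[length(x$traj)],
                           numeric(1)))
  f <- fits[[best]]$f
  traj <- fits[[best]]$traj
  out <- haps
  out$freq <- f
  out <- out[out$freq > 1e-12, , drop = FALSE]
  out$freq <- out$freq / sum(out$freq)
  rownames(out) <- NULL
  attr(out, "loglik") <- traj
  attr(out, "iterations") <- length(traj) - 1L
  out
}

#' Pairwise LD from a haplotype-frequency table
#'
#' Computes D, r2, D' and a chi-square LD p-value for one variant pair after
#' allele-vs-rest biallelic collapse: D = pAB - pA pB,
#' r2 = D^2 / (pA qA pB qB), D' = |D| / Dmax with
#' Dmax = min(pA qB, qA pB) for D > 0 and min(pA pB, qA qB) for D < 0.
#' The p-value uses the chi-square statistic n r2 with 1 df when \code{n}
#' (number of chromosomes) is supplied.
#'
#' @param freqs haplotype-frequency data frame (columns per variant plus
#'   \code{freq}), e.g. from \code{\link{em_haplotypes}}.
#' @param v1,v2 variant ids (columns of \code{freqs}).
#' @param a1,a2 focal alleles of the collapse; default the first observed.
#' @param n number of chromosomes behind the estimate (for the p-value).
#' @return list of class \code{ld_result}: pA, pB, pAB, D, r2, dprime,
#'   chisq, p.
#' @export
ld_from_haplotypes <- function(freqs, v1, v2, a1 = NULL, a2 = NULL,
                               n = NULL) {
  w <- freqs$freq / sum(freqs$freq)
  if (is.null(a1)) a1 <- freqs[[v1]][1]
  if (is.null(a2)) a2 <- freqs[[v2]][1]
  iA <- freqs[[v1]] == a1
  iB <- freqs[[v2]] == a2
  pA <- sum(w[iA]); pB <- sum(w[iB]); pAB <- sum(w[iA & iB])
  if (pA <= 0 || pA >= 1 || pB <= 0 || pB >= 1)
    stop("monomorphic collapse: r2 undefined for ", v1, ":", a1, " ~ ",
         v2, ":", a2)
  D <- pAB - pA * pB
  r2 <- D^2 / (pA * (1 - pA) * pB * (1 - pB))
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
          else min(pA * pB, (1 - pA) * (1 - pB))
  dprime <- if (D == 0) 0 else abs(D) / dmax
  chisq <- if (is.null(n)) NA_real_ else n * r2
  p <- if (is.null(n)) NA_real_ else stats::pchisq(chisq, 1,
                                                   lower.tail = FALSE)
  structure(list(v1 = v1, a1 = a1, v2 = v2, a2 = a2, pA = pA, pB = pB,
                 pAB = pAB, D = D, r2 = r2, dprime = dprime,
                 chisq = chisq, p = p),
            class = "ld_result")
}

#' @export
print.ld_result <- function(x, ...) {
  cat(sprintf("<ld_result> %s:%s ~ %s:%s  r2 = %.3f  D' = %.3f",
              x$v1, x$a1, x$v2, x$a2, x$r2, x$dprime))
  if (!is.na(x$p)) cat(sprintf("  p = %.3g", x$p))
  cat("\n")
  invisible(x)
}

#' CNV-stratified LD between a CNR and a variant
#'
#' Standard r2/D' is undefined across copy-number variable chromosomes, so
#' association between CNV and alleles is measured by partitioning
#' individuals into decreased (<= 1), normal (2) and increased (>= 3) copy
#' number of the CNR, tabulating copy-number-aware allele counts per
#' stratum, and applying Fisher's exact test to the allele-by-stratum table.
#'
#' @param genotypes genotype data frame.
#' @param cnr CNR id.
#' @param variant variant id.
#' @param locus a \code{locus_definition}.
#' @param mc_threshold total count above which a seeded Monte-Carlo p-value
#'   (1e6 draws) replaces the exact network algorithm.
#' @param seed seed for the Monte-Carlo fallback.
#' @return list: stratum allele-count table, per-stratum frequencies,
#'   p-value, method ("exact" or "monte-carlo").
#' @export
cnv_stratified_ld <- function(genotypes, cnr, variant,
                              locus = default_locus(),
                              mc_threshold = 10000, seed = 1) {
  validate_genotypes(genotypes, locus)
  copies <- as.integer(genotypes[[cnr]])
  stratum <- cut(copies, c(-Inf, 1, 2, Inf),
                 labels = c("decreased", "normal", "increased"))
  cols <- variant_columns(locus, variant)
  tab <- t(vapply(levels(stratum), function(s) {
    colSums(genotypes[stratum == s, cols, drop = FALSE])
  }, numeric(length(cols))))
  colnames(tab) <- variant_alleles(locus, variant)
  tab <- tab[rowSums(tab) > 0, colSums(tab) > 0, drop = FALSE]
  if (nrow(tab) < 2L)
    stop("all individuals fall in one copy-number stratum of ", cnr)
  if (ncol(tab) < 2L)
    stop("variant ", variant, " is monomorphic in this sample")
  if (sum(tab) <= mc_threshold) {
    p <- tryCatch(
      stats::fisher.test(tab, workspace = 2e7)$p.value,
      error = function(e) NA_real_)
    method <- "exact"
    if (is.na(p)) {
      set.seed(seed)
      p <- stats::fisher.test(tab, simulate.p.value = TRUE, B = 1e6)$p.value
      method <- "monte-carlo"
    }
  } else {
    set.seed(seed)
    p <- stats::fisher.test(tab, simulate.p.value = TRUE, B = 1e6)$p.value
    method <- "monte-carlo"
  }
  list(table = tab, frequencies = tab / rowSums(tab), p = p, method = method)
}
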