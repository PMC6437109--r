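# Synthetic cohorts: diploid populations, case-control samples under an
# additive logistic disease model, ascertained parent-offspring trios, and
# noisy MLPA-style probe-ratio tables.

#' Additive disease model
#'
#' Per-allele additive log odds ratios on the logit scale plus a baseline
#' prevalence: P(affected) = logistic(logit(prevalence) + sum over alleles of
#' dosage x logOR).
#'
#' @param log_or named numeric vector; names are genotype dosage columns
#'   (e.g. \code{FCGR2C_ORF}), values the per-copy log odds ratios.
#' @param prevalence baseline probability of disease at zero dose.
#' @return an object of class \code{disease_model}.
#' @export
disease_model <- function(log_or = numeric(0), prevalence = 0.01) {
  if (!(prevalence > 0 && prevalence < 1))
    stop("prevalence must be in (0,1)")
  if (length(log_or) && (any(!is.finite(log_or)) || is.null(names(log_or))))
    stop("log_or must be a finite named numeric vector")
  structure(list(log_or = log_or, prevalence = prevalence),
            class = "disease_model")
}

#' Disease probability under an additive model
#'
#' @param genotypes genotype data frame.
#' @param model a \code{disease_model}.
#' @return numeric vector of per-individual probabilities.
#' @export
disease_prob <- function(genotypes, model) {
  eta <- rep(stats::qlogis(model$prevalence), nrow(genotypes))
  if (length(model$log_or)) {
    miss <- setdiff(names(model$log_or), names(genotypes))
    if (length(miss))
      stop("model names dosage column(s) absent from genotypes: ",
           paste(miss, collapse = ", "))
    eta <- eta + as.matrix(genotypes[names(model$log_or)]) %*% model$log_or
  }
  as.numeric(stats::plogis(eta))
}

# draw n chromosomes (pool row indices)
draw_chromosomes <- function(pool, n) {
  if (nrow(pool) == 0L) stop("empty haplotype pool")
  sample.int(nrow(pool), n, replace = TRUE, prob = pool$freq)
}

# genotype frame from two columns of pool row indices
genotypes_from_indices <- function(pool, i1, i2, ids,
                                   locus = pool_locus(pool)) {
  C <- as.matrix(pool[, cnr_ids(locus), drop = FALSE])
  M <- pool_cache_dosage(pool, locus)
  out <- data.frame(individual_id = ids, stringsAsFactors = FALSE)
  cn <- C[i1, , drop = FALSE] + C[i2, , drop = FALSE]
  for (j in seq_along(cnr_ids(locus))) out[[cnr_ids(locus)[j]]] <- cn[, j]
  D <- M[i1, , drop = FALSE] + M[i2, , drop = FALSE]
  for (j in seq_len(ncol(D))) out[[colnames(M)[j]]] <- D[, j]
  attr(out, "diplotypes") <- cbind(i1, i2)
  attr(out, "pool") <- pool
  out
}

# memoized dosage matrix per pool object
pool_cache_dosage <- function(pool, locus = pool_locus(pool)) {
  m <- attr(pool, ".dosage_matrix")
  if (is.null(m)) m <- pool_dosage_matrix(pool, locus)
  m
}

#' Sample a diploid population from a pool
#'
#' Each individual is two independent chromosome draws from the pool,
#' combined into an unphased genotype.
#'
#' @param pool a \code{hap_pool}.
#' @param n number of individuals (>= 1).
#' @param seed integer seed.
#' @return genotype data frame; the true diplotypes (pool row indices) are
#'   kept in \code{attr(, "diplotypes")}.
#' @export
sample_population <- function(pool, n, seed = NULL) {
  if (n < 1) stop("n must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  i1 <- draw_chromosomes(pool, n)
  i2 <- draw_chromosomes(pool, n)
  genotypes_from_indices(pool, i1, i2, sprintf("ind%04d", seq_len(n)))
}

#' Sample a case-control dataset under an additive disease model
#'
#' Individuals are drawn from the pool and assigned affected status with
#' probability given by the additive logistic model; sampling continues until
#' both quotas are filled.
#'
#' @param pool a \code{hap_pool}.
#' @param model a \code{disease_model}.
#' @param n_case,n_control quotas (>= 1).
#' @param seed integer seed.
#' @param max_draws cap on total individuals drawn before giving up (guards
#'   against extreme prevalence).
#' @return list with genotype frames \code{cases} and \code{controls}.
#' @export
sample_case_control <- function(pool, model, n_case, n_control, seed = NULL,
                                max_draws = 500 * (n_case + n_control)) {
  if (n_case < 1 || n_control < 1) stop("quotas must be >= 1")
  stopifnot(inherits(model, "disease_model"))
  if (!is.null(seed)) set.seed(seed)
  ca1 <- ca2 <- co1 <- co2 <- integer(0)
  drawn <- 0L
  while ((length(ca1) < n_case || length(co1) < n_control)) {
    if (drawn >= max_draws)
      stop("case/control quotas not filled after ", drawn,
           " draws; prevalence too extreme for rejection sampling")
    k <- min(max(1000L, 2L * (n_case + n_control)), max_draws - drawn)
    drawn <- drawn + k
    i1 <- draw_chromosomes(pool, k)
    i2 <- draw_chromosomes(pool, k)
    g <- genotypes_from_indices(pool, i1, i2, rep("tmp", k))
    aff <- stats::runif(k) < disease_prob(g, model)
    ca1 <- c(ca1, i1[aff]); ca2 <- c(ca2, i2[aff])
    co1 <- c(co1, i1[!aff]); co2 <- c(co2, i2[!aff])
  }
  list(
    cases = genotypes_from_indices(pool, ca1[seq_len(n_case)],
                                   ca2[seq_len(n_case)],
                                   sprintf("case%04d", seq_len(n_case))),
    controls = genotypes_from_indices(pool, co1[seq_len(n_control)],
                                      co2[seq_len(n_control)],
                                      sprintf("ctrl%04d", seq_len(n_control)))
  )
}

#' Sample parent-offspring trios ascertained on an affected child
#'
#' Parents are drawn from the pool; the child receives one uniformly chosen
#' chromosome from each parent; families are retained with probability equal
#' to the child's disease probability (single-affected-child ascertainment).
#' Under a null model transmissions are 50/50.
#'
#' @param pool a \code{hap_pool}.
#' @param model a \code{disease_model}, or \code{NULL} for unascertained
#'   (null) trios.
#' @param n_trios number of families (>= 1).
#' @param seed integer seed.
#' @param max_draws cap on candidate families drawn.
#' @return PED-like data frame (columns family_id, individual_id, father_id,
#'   mother_id, affected, then the genotype columns; three rows per family).
#'   True phase is kept in \code{attr(, "truth")}: pool row indices of each
#'   parent's transmitted and untransmitted chromosome.
#' @export
sample_trios <- function(pool, model = NULL, n_trios, seed = NULL,
                         max_draws = 2000 * n_trios) {
  if (n_trios < 1) stop("n_trios must be >= 1")
  if (!is.null(seed)) set.seed(seed)
  locus <- pool_locus(pool)
  ft <- fu <- mt <- mu <- integer(0)
  drawn <- 0L
  while (length(ft) < n_trios) {
    if (drawn >= max_draws)
      stop("trio quota not filled after ", drawn,
           " draws; prevalence too extreme for rejection sampling")
    k <- min(max(1000L, 2L * n_trios), max_draws - drawn)
    drawn <- drawn + k
    f1 <- draw_chromosomes(pool, k); f2 <- draw_chromosomes(pool, k)
    m1 <- draw_chromosomes(pool, k); m2 <- draw_chromosomes(pool, k)
    pick_f <- stats::runif(k) < 0.5
    pick_m <- stats::runif(k) < 0.5
    c_f <- ifelse(pick_f, f1, f2); c_fu <- ifelse(pick_f, f2, f1)
    c_m <- ifelse(pick_m, m1, m2); c_mu <- ifelse(pick_m, m2, m1)
    if (is.null(model)) {
      keep <- rep(TRUE, k)
    } else {
      child <- genotypes_from_indices(pool, c_f, c_m, rep("tmp", k))
      keep <- stats::runif(k) < disease_prob(child, model)
    }
    ft <- c(ft, c_f[keep]); fu <- c(fu, c_fu[keep])
    mt <- c(mt, c_m[keep]); mu <- c(mu, c_mu[keep])
  }
  idx <- seq_len(n_trios)
  ft <- ft[idx]; fu <- fu[idx]; mt <- mt[idx]; mu <- mu[idx]
  fam <- sprintf("fam%04d", idx)
  fathers <- genotypes_from_indices(pool, ft, fu, paste0(fam, "_F"))
  mothers <- genotypes_from_indices(pool, mt, mu, paste0(fam, "_M"))
  children <- genotypes_from_indices(pool, ft, mt, paste0(fam, "_C"))
  ped_cols <- function(g, fam, father, mother, affected) {
    cbind(data.frame(family_id = fam, individual_id = g$individual_id,
                     father_id = father, mother_id = mother,
                     affected = affected, stringsAsFactors = FALSE),
          g[, -1, drop = FALSE])
  }
  out <- rbind(
    ped_cols(fathers, fam, "0", "0", 1L),
    ped_cols(mothers, fam, "0", "0", 1L),
    ped_cols(children, fam, fathers$individual_id, mothers$individual_id, 2L))
  out <- out[order(out$family_id, out$individual_id), ]
  rownames(out) <- NULL
  attr(out, "truth") <- data.frame(
    family_id = fam, father_transmitted = ft, father_untransmitted = fu,
    mother_transmitted = mt, mother_untransmitted = mu,
    stringsAsFactors = FALSE)
  attr(out, "pool") <- pool
  out
}

# internal FCGR2C dosage counts (Stop1/Stop2/ORF/NCORF) per pool chromosome
pool_fcgr2c_internal <- function(pool) {
  parts <- strsplit(pool$FCGR2C_HAP, ALLELE_SEP, fixed = TRUE)
  t(vapply(parts, function(a)
    vapply(.fcgr2c_internal, function(l) sum(a == l), integer(1)),
    integer(length(.fcgr2c_internal))))
}

#' Simulate MLPA probe ratios
#'
#' Inverse of the MLPA caller: for every CNR reference probe the normalized
#' ratio is copies/2 plus Gaussian noise, and for every allele-specific probe
#' dosage/2 plus noise (1.0 = two copies). FCGR2C is assayed through two
#' dosage probes (the Q57X open-reading-frame site and the intron-7 splice
#' site) and the FCGR2B/FCGR2C promoters through combined 2B.1/2B.2/2B.4
#' probes, mirroring the paralog-ambiguous chemistry at the locus.
#'
#' @param genotypes genotype frame; if it carries true diplotypes (from the
#'   samplers) the internal FCGR2C splice status is taken from them,
#'   otherwise all Stop copies are treated as splice-intact.
#' @param noise_sd Gaussian noise standard deviation on the ratio scale
#'   (>= 0; 0 gives exact ratios).
#' @param seed integer seed.
#' @param probes_per_cnr reference probes per CNR.
#' @param replicates independent measurements per probe (MLPA assays are
#'   conventionally run in duplicate; the caller uses the median across
#'   replicates and probes).
#' @param locus a \code{locus_definition}.
#' @return long data frame: individual_id, probe_id, target, ratio.
#' @export
simulate_mlpa <- function(genotypes, noise_sd = 0.05, seed = NULL,
                          probes_per_cnr = 2, replicates = 2,
                          locus = default_locus()) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(genotypes)
  ids <- genotypes$individual_id
  dip <- attr(genotypes, "diplotypes")
  pool <- attr(genotypes, "pool")
  if (!is.null(dip) && nrow(dip) != n) dip <- NULL  # stale after subsetting
  if (!is.null(dip) && !is.null(pool)) {
    I <- pool_fcgr2c_internal(pool)
    internal <- I[dip[, 1], , drop = FALSE] + I[dip[, 2], , drop = FALSE]
  } else {
    internal <- cbind(Stop1 = genotypes$FCGR2C_Stop, Stop2 = 0L,
                      ORF = genotypes$FCGR2C_ORF, NCORF = genotypes$FCGR2C_NCORF)
  }
  rows <- list()
  add <- function(target, probe, value) {
    for (r in seq_len(replicates))
      rows[[length(rows) + 1L]] <<- data.frame(
        individual_id = ids, probe_id = paste0(probe, "_r", r),
        target = target,
        ratio = value / 2 +
          if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0,
        stringsAsFactors = FALSE)
  }
  for (cnr in cnr_ids(locus))
    for (p in seq_len(probes_per_cnr))
      add(cnr, sprintf("%s_p%d", cnr, p), genotypes[[cnr]])
  direct <- setdiff(names(locus$variants),
                    c("FCGR2C_HAP", "FCGR2C_PROM", "FCGR2B_PROM"))
  for (v in direct) {
    cols <- variant_columns(locus, v)
    for (j in seq_along(cols))
      add(paste0(v, ":", variant_alleles(locus, v)[j]),
          paste0(cols[j], "_p1"), genotypes[[cols[j]]])
  }
  add("FCGR2C:ORFSNP", "FCGR2C_ORFSNP_p1",
      internal[, "ORF"] + internal[, "NCORF"])
  add("FCGR2C:SPLICE", "FCGR2C_SPLICE_p1",
      internal[, "NCORF"] + internal[, "Stop2"])
  for (a in c("2B.1", "2B.2", "2B.4"))
    add(paste0("PROM:", a), paste0("PROM_", a, "_p1"),
        genotypes[[paste0("FCGR2C_", a)]] + genotypes[[paste0("FCGR2B_", a)]])
  out <- do.call(rbind, rows)
  out <- out[order(match(out$individual_id, ids)), ]
  rownames(out) <- NULL
  out
}
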