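# Interpretation of MLPA-style dosage ratios: copy-number calls, allele
# dosages, FCGR2C haplotype resolution, promoter allocation, and exact
# misclassification rates of the calling rules.

#' Call a copy number from probe ratios
#'
#' copies = round(2 x median ratio); a no-call (NA) is returned when the
#' doubled median is farther than \code{margin} (in copy units) from an
#' integer.
#'
#' @param ratios numeric vector of normalized probe ratios (1.0 = 2 copies).
#' @param margin no-call margin in copy units.
#' @return integer copy number, or NA for a no-call.
#' @export
call_copy_number <- function(ratios, margin = 0.2) {
  if (length(ratios) == 0L) stop("no probe ratios supplied")
  x <- 2 * stats::median(ratios)
  k <- round(x)
  if (abs(x - k) > margin) return(NA_integer_)
  as.integer(max(0, k))
}

#' Default per-copy FCGR2C haplotype priors
#'
#' Per-copy frequencies of the four internal FCGR2C haplotypes in a pool
#' (dosage-weighted over all chromosomes), used to rank ambiguous
#' configurations.
#'
#' @param pool a \code{hap_pool}; defaults to the European pool.
#' @return named numeric over Stop1/Stop2/ORF/NCORF, summing to 1.
#' @export
fcgr2c_priors <- function(pool = population_pool("EUR")) {
  m <- pool_marginals(pool, "FCGR2C_HAP", cnv_free = FALSE, internal = TRUE)
  full <- stats::setNames(rep(0, length(.fcgr2c_internal)), .fcgr2c_internal)
  full[names(m)] <- m
  full / sum(full)
}

#' Resolve FCGR2C haplotype counts from dosages
#'
#' Enumerates every multiset of per-copy internal haplotypes (Stop with
#' intact splice, Stop with splice mutation, classic ORF, nonclassic ORF)
#' consistent with the gene copy number, the open-reading-frame dosage at
#' the Q57X site, and the splice-site mutant dosage. If the collapsed
#' Stop/ORF/NCORF configuration is unique it is returned with posterior 1;
#' otherwise the maximum-posterior configuration under the priors is
#' returned with the ambiguity flag set (ties broken toward more Stop
#' haplotypes).
#'
#' @param n_copies FCGR2C gene copy number.
#' @param orf_dosage copies carrying an open reading frame at the stop-codon
#'   site (classic + nonclassic ORF).
#' @param splice_dosage copies carrying the intron-7 splice-site mutation
#'   (nonclassic ORF + splice-mutant Stop).
#' @param priors named numeric over the internal haplotypes.
#' @return list with \code{counts} (named Stop/ORF/NCORF, summing to
#'   n_copies), \code{ambiguous}, \code{posterior}.
#' @export
resolve_fcgr2c <- function(n_copies, orf_dosage, splice_dosage,
                           priors = fcgr2c_priors()) {
  if (orf_dosage > n_copies || splice_dosage > n_copies)
    stop("dosage exceeds FCGR2C copy number (", orf_dosage, "/",
         splice_dosage, " vs ", n_copies, " copies)")
  if (min(n_copies, orf_dosage, splice_dosage) < 0)
    stop("negative input")
  pr <- priors[.fcgr2c_internal]
  pr[is.na(pr)] <- 0
  lo <- max(0L, orf_dosage + splice_dosage - n_copies)
  hi <- min(orf_dosage, splice_dosage)
  configs <- lapply(lo:hi, function(nc) {
    classic <- orf_dosage - nc
    stop2 <- splice_dosage - nc
    stop1 <- n_copies - classic - stop2 - nc
    if (stop1 < 0) return(NULL)
    cnt <- c(Stop1 = stop1, Stop2 = stop2, ORF = classic, NCORF = nc)
    # multinomial weight of the multiset under iid per-copy priors
    w <- exp(lgamma(n_copies + 1) - sum(lgamma(cnt + 1))) *
      prod(ifelse(cnt > 0, pr[names(cnt)]^cnt, 1))
    list(counts = c(Stop = stop1 + stop2, ORF = classic, NCORF = nc), w = w)
  })
  configs <- Filter(Negate(is.null), configs)
  if (!length(configs)) stop("no FCGR2C configuration consistent with input")
  keys <- vapply(configs, function(cf) paste(cf$counts, collapse = ","),
                 character(1))
  w <- vapply(configs, function(cf) cf$w, numeric(1))
  wsum <- tapply(w, keys, sum)
  uniq <- !duplicated(keys)
  groups <- configs[uniq]
  gw <- as.numeric(wsum[keys[uniq]])
  if (all(gw == 0)) gw <- rep(1, length(gw))  # uninformative priors
  nstop <- vapply(groups, function(cf) cf$counts[["Stop"]], numeric(1))
  best <- order(-gw, -nstop)[1]
  list(counts = groups[[best]]$counts,
       ambiguous = length(groups) > 1L,
       posterior = gw[best] / sum(gw))
}

#' Allocate promoter haplotype dosages between FCGR2B and FCGR2C
#'
#' The paralogous FCGR2B/FCGR2C promoters are sequence-identical, so MLPA
#' observes only combined 2B.2 and 2B.4 dosages. The allocation rule assigns
#' 2B.2 to FCGR2C and 2B.4 to FCGR2B (where they almost always reside), with
#' 2B.1 as the remainder; dosage exceeding the target gene's copy number
#' spills to the other gene and raises the ambiguity flag.
#'
#' @param total_2B2,total_2B4 combined dosages across both genes.
#' @param fcgr2b_copies,fcgr2c_copies per-gene copy numbers.
#' @return list with named count vectors \code{FCGR2C} and \code{FCGR2B}
#'   (over 2B.1/2B.2/2B.4) and \code{flagged}.
#' @export
allocate_promoter <- function(total_2B2, total_2B4, fcgr2b_copies = 2,
                              fcgr2c_copies = 2) {
  if (min(total_2B2, total_2B4) < 0) stop("negative dosage")
  if (total_2B2 + total_2B4 > fcgr2b_copies + fcgr2c_copies)
    stop("promoter dosages exceed combined FCGR2B+FCGR2C copies")
  c2 <- min(total_2B2, fcgr2c_copies)
  b2 <- total_2B2 - c2
  b4 <- min(total_2B4, fcgr2b_copies - b2)
  c4 <- total_2B4 - b4
  list(FCGR2C = c(`2B.1` = fcgr2c_copies - c2 - c4, `2B.2` = c2, `2B.4` = c4),
       FCGR2B = c(`2B.1` = fcgr2b_copies - b2 - b4, `2B.2` = b2, `2B.4` = b4),
       flagged = (b2 > 0 || c4 > 0))
}

#' Call genotypes from a probe-ratio table
#'
#' Full interpretation pipeline: per-CNR copy number from reference probes,
#' allele dosages from allele-specific probes, FCGR2C haplotype resolution
#' from the ORF and splice-site dosage probes, and promoter allocation from
#' the combined promoter probes.
#'
#' @param probes long data frame with columns individual_id, probe_id,
#'   target, ratio (the dialect written by \code{\link{simulate_mlpa}}).
#' @param locus a \code{locus_definition}.
#' @param priors per-copy FCGR2C priors for ambiguity resolution.
#' @param margin no-call margin in copy units.
#' @return genotype data frame; per-individual call metadata (no-call,
#'   ambiguity and allocation flags, FCGR2C posterior) in
#'   \code{attr(, "calls")}.
#' @export
call_genotypes <- function(probes, locus = default_locus(),
                           priors = fcgr2c_priors(), margin = 0.2) {
  ids <- unique(probes$individual_id)
  rows <- vector("list", length(ids))
  meta <- vector("list", length(ids))
  bygroup <- split(probes, probes$individual_id)
  for (i in seq_along(ids)) {
    p <- bygroup[[ids[i]]]
    byt <- split(p$ratio, p$target)
    cc <- function(target) {
      r <- byt[[target]]
      if (is.null(r)) return(NA_integer_)
      call_copy_number(r, margin)
    }
    cn <- vapply(cnr_ids(locus), cc, integer(1))
    row <- as.list(cn)
    nocall <- any(is.na(cn))
    fcgr2c_ambig <- FALSE; prom_flag <- FALSE; post <- NA_real_
    if (!nocall) {
      gcopies <- vapply(locus$genes, function(g) {
        k <- 2L + sum(cn[cnrs_containing(locus, g)] - 2L)
        k
      }, integer(1))
      direct <- setdiff(names(locus$variants),
                        c("FCGR2C_HAP", "FCGR2C_PROM", "FCGR2B_PROM"))
      for (v in direct) {
        alle <- variant_alleles(locus, v)
        d <- vapply(paste0(v, ":", alle), cc, integer(1))
        if (any(is.na(d)) ||
            sum(d) != gcopies[[variant_gene(locus, v)]]) {
          nocall <- TRUE
        } else {
          row[variant_columns(locus, v)] <- as.list(as.integer(d))
        }
      }
      orf_d <- cc("FCGR2C:ORFSNP"); spl_d <- cc("FCGR2C:SPLICE")
      d22 <- cc("PROM:2B.2"); d24 <- cc("PROM:2B.4")
      if (any(is.na(c(orf_d, spl_d, d22, d24)))) nocall <- TRUE
      if (!nocall) {
        res <- resolve_fcgr2c(gcopies[["FCGR2C"]], orf_d, spl_d, priors)
        row[variant_columns(locus, "FCGR2C_HAP")] <-
          as.list(as.integer(res$counts[variant_alleles(locus, "FCGR2C_HAP")]))
        fcgr2c_ambig <- res$ambiguous; post <- res$posterior
        al <- allocate_promoter(d22, d24, gcopies[["FCGR2B"]],
                                gcopies[["FCGR2C"]])
        row[variant_columns(locus, "FCGR2C_PROM")] <-
          as.list(as.integer(al$FCGR2C[variant_alleles(locus, "FCGR2C_PROM")]))
        row[variant_columns(locus, "FCGR2B_PROM")] <-
          as.list(as.integer(al$FCGR2B[variant_alleles(locus, "FCGR2B_PROM")]))
        prom_flag <- al$flagged
      }
    }
    rows[[i]] <- c(list(individual_id = ids[i]), row)
    meta[[i]] <- data.frame(individual_id = ids[i], nocall = nocall,
                            fcgr2c_ambiguous = fcgr2c_ambig,
                            promoter_flagged = prom_flag,
                            fcgr2c_posterior = post,
                            stringsAsFactors = FALSE)
  }
  cols <- genotype_columns(locus)
  out <- do.call(rbind, lapply(rows, function(r) {
    miss <- setdiff(cols, names(r))
    for (mcol in miss) r[[mcol]] <- NA_integer_
    as.data.frame(r[cols], check.names = FALSE, optional = TRUE,
                  stringsAsFactors = FALSE)
  }))
  names(out) <- cols
  rownames(out) <- NULL
  attr(out, "calls") <- do.call(rbind, meta)
  out
}

#' Exact misclassification rate of a calling rule
#'
#' Frequency-weighted enumeration over all diplotypes of the pool of the
#' event "rule output differs from the true configuration". For the FCGR2C
#' rule the observables are (copy number, ORF dosage, splice dosage); for
#' the promoter rule the combined 2B.2/2B.4 dosages and per-gene copy
#' numbers.
#'
#' @param pool a \code{hap_pool} (with internal FCGR2C labels).
#' @param rule \code{"resolve_fcgr2c"} or \code{"allocate_promoter"}.
#' @param priors per-copy FCGR2C priors; default derived from \code{pool}.
#' @return misclassification probability in [0, 1].
#' @export
estimate_misclassification <- function(pool,
                                       rule = c("resolve_fcgr2c",
                                                "allocate_promoter"),
                                       priors = NULL) {
  rule <- match.arg(rule)
  if (rule == "resolve_fcgr2c") {
    if (is.null(priors)) priors <- fcgr2c_priors(pool)
    I <- pool_fcgr2c_internal(pool)
    key <- apply(I, 1, paste, collapse = ",")
    w <- tapply(pool$freq, key, sum)
    sig <- I[!duplicated(key), , drop = FALSE]
    w <- as.numeric(w[key[!duplicated(key)]])
    rate <- 0
    for (i in seq_len(nrow(sig))) for (j in seq_len(nrow(sig))) {
      cnt <- sig[i, ] + sig[j, ]
      truth <- c(Stop = unname(cnt["Stop1"] + cnt["Stop2"]),
                 ORF = unname(cnt["ORF"]), NCORF = unname(cnt["NCORF"]))
      res <- resolve_fcgr2c(sum(cnt), cnt[["ORF"]] + cnt[["NCORF"]],
                            cnt[["NCORF"]] + cnt[["Stop2"]], priors)
      if (any(res$counts != truth)) rate <- rate + w[i] * w[j]
    }
    return(rate)
  }
  # promoter allocation
  locus <- pool_locus(pool)
  M <- pool_cache_dosage(pool, locus)
  kC <- pool_gene_copies(pool, "FCGR2C", locus)
  cols <- c(paste0("FCGR2C_", c("2B.1", "2B.2", "2B.4")),
            paste0("FCGR2B_", c("2B.1", "2B.2", "2B.4")))
  key <- paste(kC, apply(M[, cols, drop = FALSE], 1, paste, collapse = ","))
  w <- tapply(pool$freq, key, sum)
  first <- !duplicated(key)
  sig <- cbind(kC, M[, cols, drop = FALSE])[first, , drop = FALSE]
  w <- as.numeric(w[key[first]])
  rate <- 0
  for (i in seq_len(nrow(sig))) for (j in seq_len(nrow(sig))) {
    s <- sig[i, ] + sig[j, ]
    truthC <- s[2:4]; truthB <- s[5:7]
    al <- allocate_promoter(s[["FCGR2C_2B.2"]] + s[["FCGR2B_2B.2"]],
                            s[["FCGR2C_2B.4"]] + s[["FCGR2B_2B.4"]],
                            fcgr2b_copies = 2, fcgr2c_copies = s[["kC"]])
    if (any(al$FCGR2C != truthC) || any(al$FCGR2B != truthB))
      rate <- rate + w[i] * w[j]
  }
  rate
}
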