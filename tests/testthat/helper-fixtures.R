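# Shared fixtures: small pools, random haplotypes, and independent oracles.

# cached default European pool (built once per test run)
eur_pool <- local({
  pool <- NULL
  function() {
    if (is.null(pool)) pool <<- population_pool("EUR")
    pool
  }
})

# pool over one or two variant systems, everything else monomorphic
toy_pool <- function(marginals, ld_targets = NULL, cnr_freqs = NULL, ...) {
  build_pool(marginals, ld_targets, cnr_freqs, ...)
}

# random chromosome haplotype on the default locus (optionally with CNV)
random_haplotype <- function(locus = default_locus(), cnv = TRUE) {
  repeat {
    cnr <- vapply(fcgrhap:::cnr_ids(locus), function(id)
      if (cnv) sample(0:2, 1, prob = c(.1, .8, .1)) else 1L, numeric(1))
    kk <- vapply(locus$genes, function(g)
      fcgrhap:::chrom_gene_copies(cnr, g, locus), integer(1))
    if (all(kk >= 0)) break
  }
  alleles <- lapply(names(locus$variants), function(v) {
    g <- fcgrhap:::variant_gene(locus, v)
    k <- fcgrhap:::chrom_gene_copies(cnr, g, locus)
    sample(fcgrhap:::variant_alleles(locus, v), k, replace = TRUE)
  })
  names(alleles) <- names(locus$variants)
  chrom_haplotype(cnr, alleles, locus)
}

# Independent maximum-likelihood oracle for two-variant haplotype
# frequencies: direct numerical maximization of the observed-data
# multinomial likelihood over the simplex (softmax parametrization,
# several starts), with hard phase assignments as additional candidates.
brute_force_ml <- function(genotypes, variants, locus = default_locus()) {
  pairs <- lapply(variants, function(v)
    fcgrhap:::genotype_pairs(genotypes, v, locus))
  names(pairs) <- variants
  alle <- lapply(variants, function(v) sort(unique(as.vector(pairs[[v]]))))
  names(alle) <- variants
  haps <- expand.grid(alle, stringsAsFactors = FALSE)
  hap_key <- do.call(paste, c(haps, sep = "|"))
  n <- nrow(genotypes)
  phase_sets <- lapply(seq_len(n), function(i) {
    per_var <- lapply(variants, function(v) {
      a <- pairs[[v]][i, ]
      if (a[1] == a[2]) list(a) else list(a, rev(a))
    })
    combos <- expand.grid(lapply(per_var, seq_along))
    unique(t(apply(combos, 1, function(ci) {
      h1 <- vapply(seq_along(variants),
                   function(j) per_var[[j]][[ci[j]]][1], character(1))
      h2 <- vapply(seq_along(variants),
                   function(j) per_var[[j]][[ci[j]]][2], character(1))
      sort(c(match(paste(h1, collapse = "|"), hap_key),
             match(paste(h2, collapse = "|"), hap_key)))
    })))
  })
  ll <- function(f) {
    f <- pmax(f, 1e-300)
    sum(vapply(phase_sets, function(ph)
      log(sum(apply(ph, 1, function(hp)
        f[hp[1]] * f[hp[2]] * (2 - (hp[1] == hp[2]))))), numeric(1)))
  }
  softmax <- function(theta) { e <- exp(c(0, theta)); e / sum(e) }
  K <- nrow(haps)
  best <- NULL
  starts <- c(list(rep(0, K - 1)),
              lapply(1:5, function(s) stats::rnorm(K - 1, 0, 2)))
  # hard phase assignments as extra starts
  hard <- expand.grid(lapply(phase_sets, function(ph) seq_len(nrow(ph))))
  if (nrow(hard) <= 256) {
    for (r in seq_len(nrow(hard))) {
      cnt <- numeric(K)
      for (i in seq_len(n)) {
        hp <- phase_sets[[i]][hard[r, i], ]
        cnt[hp[1]] <- cnt[hp[1]] + 1; cnt[hp[2]] <- cnt[hp[2]] + 1
      }
      f0 <- pmax(cnt / (2 * n), 1e-6)
      starts <- c(starts, list(log(f0[-1] / f0[1])))
    }
  }
  for (th0 in starts) {
    op <- stats::optim(th0, function(th) -ll(softmax(th)),
                       method = "BFGS",
                       control = list(maxit = 500, reltol = 1e-14))
    if (is.null(best) || -op$value > best$ll)
      best <- list(ll = -op$value, f = softmax(op$par))
  }
  out <- haps
  out$freq <- best$f
  attr(out, "loglik") <- best$ll
  out
}

# expand a printed dose-count table into a genotype-free dose/status pair
expand_doses <- function(doses, case_counts, control_counts) {
  list(dose = c(rep(doses, case_counts), rep(doses, control_counts)),
       status = c(rep(1L, sum(case_counts)), rep(0L, sum(control_counts))))
}
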