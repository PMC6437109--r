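# Mendelian phasing of parent-offspring trios over the CNV locus into
# chromosome-level haplotypes, and the allele-wise transmission
# disequilibrium test.

# ordered splits of a per-individual CNR total into two per-chromosome
# copy counts (each 0..2). The parsimonious set keeps at least one
# chromosome at baseline (1 copy) where possible; `exotic = TRUE` also
# enumerates deletion+duplication carriers (e.g. total 2 as 0+2), which are
# rare and only needed when parsimonious phasing fails Mendelian matching.
cnr_splits <- function(total, exotic = FALSE) {
  a <- 0:2
  out <- expand.grid(c1 = a, c2 = a)
  out <- out[out$c1 + out$c2 == total, , drop = FALSE]
  if (!exotic) {
    keep <- out$c1 == 1L | out$c2 == 1L
    if (!any(keep)) keep <- rep(TRUE, nrow(out))  # totals 0 and 4
    out <- out[keep, , drop = FALSE]
  }
  out
}

# all sub-dosage vectors d1 with 0 <= d1 <= d and sum(d1) == k
dose_splits <- function(d, k) {
  if (k < 0 || k > sum(d)) return(list())
  grid <- expand.grid(lapply(d, function(x) 0:x))
  grid <- grid[rowSums(grid) == k, , drop = FALSE]
  lapply(seq_len(nrow(grid)), function(i) as.integer(grid[i, ]))
}

# chromosome record: named list(cnr = int vector, hap = named character of
# per-variant display strings); key = canonical string
chrom_key <- function(cnr, hap) {
  paste(paste(cnr, collapse = ","), paste(hap, collapse = "|"), sep = ";")
}

# prior lookup (collapsed display-form keys -> frequency) built from a pool
build_prior_lookup <- function(pool, locus = pool_locus(pool)) {
  ids <- cnr_ids(locus)
  cnr_part <- do.call(paste, c(lapply(ids, function(id) pool[[id]]),
                               list(sep = ",")))
  hap_cols <- lapply(names(locus$variants), function(v)
    vapply(strsplit(pool[[v]], ALLELE_SEP, fixed = TRUE), hap_string,
           character(1)))
  hap_part <- do.call(paste, c(hap_cols, list(sep = "|")))
  key <- paste(cnr_part, hap_part, sep = ";")
  freq <- rowsum(pool$freq, key)
  stats::setNames(as.numeric(freq), rownames(freq))
}

# all diplotype decompositions of one genotype row; returns list of
# list(k1, k2, w, rec1, rec2) with prior weights from `lookup`
individual_decompositions <- function(row, locus, lookup, floor = 1e-9,
                                      cache = NULL, exotic = FALSE) {
  sig <- paste(paste(unlist(row[genotype_columns(locus)[-1]]),
                     collapse = ","), exotic)
  if (!is.null(cache) && !is.null(cache[[sig]])) return(cache[[sig]])
  ids <- cnr_ids(locus)
  splits_per_cnr <- lapply(ids, function(cnr) cnr_splits(row[[cnr]], exotic))
  combos <- expand.grid(lapply(splits_per_cnr, function(s) seq_len(nrow(s))))
  out <- list()
  for (ci in seq_len(nrow(combos))) {
    c1 <- vapply(seq_along(ids), function(j)
      splits_per_cnr[[j]]$c1[combos[ci, j]], integer(1))
    c2 <- vapply(seq_along(ids), function(j)
      splits_per_cnr[[j]]$c2[combos[ci, j]], integer(1))
    names(c1) <- names(c2) <- ids
    ok <- TRUE
    per_var <- list()
    for (v in names(locus$variants)) {
      gene <- variant_gene(locus, v)
      k1 <- chrom_gene_copies(c1, gene, locus)
      k2 <- chrom_gene_copies(c2, gene, locus)
      if (k1 < 0L || k2 < 0L || k1 > 2L + length(ids) || k2 > 2L + length(ids)) {
        ok <- FALSE; break
      }
      d <- as.integer(row[variant_columns(locus, v)])
      sp <- dose_splits(d, k1)
      if (!length(sp)) { ok <- FALSE; break }
      per_var[[v]] <- list(d = d, sp = sp)
    }
    if (!ok) next
    vcombos <- expand.grid(lapply(per_var, function(pv) seq_along(pv$sp)))
    for (vi in seq_len(nrow(vcombos))) {
      hap1 <- hap2 <- character(length(per_var))
      names(hap1) <- names(hap2) <- names(per_var)
      for (v in names(per_var)) {
        alle <- variant_alleles(locus, v)
        d1 <- per_var[[v]]$sp[[vcombos[vi, v]]]
        d2 <- per_var[[v]]$d - d1
        hap1[v] <- hap_string(rep(alle, d1))
        hap2[v] <- hap_string(rep(alle, d2))
      }
      k1 <- chrom_key(c1, hap1); k2 <- chrom_key(c2, hap2)
      pair_key <- paste(sort(c(k1, k2)), collapse = "~")
      if (!is.null(out[[pair_key]])) next
      w <- max(lookup[k1], floor, na.rm = TRUE) *
        max(lookup[k2], floor, na.rm = TRUE)
      out[[pair_key]] <- list(k1 = k1, k2 = k2, w = w,
                              rec1 = list(cnr = c1, hap = hap1),
                              rec2 = list(cnr = c2, hap = hap2))
    }
  }
  out <- unname(out)
  if (!is.null(cache)) cache[[sig]] <- out
  out
}

#' Phase parent-offspring trios into chromosome-level haplotypes
#'
#' For every trio, enumerates all diplotype decompositions of father, mother
#' and child consistent with their CNR copy numbers and allele dosages,
#' keeps the combinations in which the child's two chromosomes are one from
#' each parent, and reports each parent's transmitted and untransmitted
#' chromosome. When several combinations survive, the one with maximum
#' parental-diplotype prior probability (then lexicographic key order) is
#' chosen and flagged ambiguous; Mendelian inconsistency yields a flagged
#' no-call record, not an error.
#'
#' @param trios PED-like data frame from \code{\link{sample_trios}} or
#'   \code{\link{read_trios}}.
#' @param pool \code{hap_pool} supplying haplotype priors.
#' @param locus a \code{locus_definition}.
#' @param ambig_tol solutions whose relative posterior weight falls below
#'   this fraction of the total are ignored when deciding ambiguity (they
#'   can still never be selected over a heavier solution). Solutions are
#'   grouped by the parent-symmetric multiset of labeled chromosomes
#'   (transmitted/untransmitted), under which every per-marker T/U count is
#'   invariant, so a pure parent-swap does not count as ambiguity.
#' @param cache a \code{\link{phase_cache}} environment; supply one to
#'   reuse prior lookups and solved trio configurations across repeated
#'   calls (simulation studies).
#' @return data frame with one row per parental chromosome (columns
#'   family_id, parent, transmitted, the per-CNR copy counts, one display
#'   string column per variant, ambiguous, posterior, mendel_ok).
#' @export
phase_trios <- function(trios, pool = population_pool("EUR"),
                        locus = default_locus(), ambig_tol = 1e-3,
                        cache = NULL) {
  if (is.null(cache)) cache <- phase_cache(pool, locus)
  lookup <- cache$lookup
  dcache <- cache$decomp
  trio_cache <- cache$trio

  # hash one parent's decompositions: chromosome key -> candidate
  # transmissions (untransmitted record + pair weight)
  index_parent <- function(decomps) {
    h <- new.env(parent = emptyenv())
    push <- function(key, un, w) {
      h[[key]] <- c(h[[key]], list(list(un = un, w = w)))
    }
    for (d in decomps) {
      push(d$k1, d$rec2, d$w)
      if (d$k1 != d$k2) push(d$k2, d$rec1, d$w)
    }
    h
  }

  match_solutions <- function(fd, md, cd) {
      fh <- index_parent(fd); mh <- index_parent(md)
      groups <- new.env(parent = emptyenv())  # signature -> [weight, cand]
      for (cc in cd) {
        orientations <- if (cc$k1 == cc$k2) list(1:2) else list(1:2, 2:1)
        for (orient in orientations) {
          ck_f <- c(cc$k1, cc$k2)[orient[1]]
          ck_m <- c(cc$k1, cc$k2)[orient[2]]
          rec_f <- list(cc$rec1, cc$rec2)[[orient[1]]]
          rec_m <- list(cc$rec1, cc$rec2)[[orient[2]]]
          fms <- fh[[ck_f]]; mms <- mh[[ck_m]]
          if (is.null(fms) || is.null(mms)) next
          for (fm in fms) for (mm in mms) {
            fu_key <- chrom_key(fm$un$cnr, fm$un$hap)
            mu_key <- chrom_key(mm$un$cnr, mm$un$hap)
            sig <- paste(sort(c(paste0("t|", ck_f), paste0("t|", ck_m),
                                paste0("u|", fu_key), paste0("u|", mu_key))),
                         collapse = "##")
            w <- fm$w * mm$w
            g <- groups[[sig]]
            if (is.null(g)) {
              groups[[sig]] <- list(w = w, best_w = w,
                                    cand = list(f_t = rec_f, f_u = fm$un,
                                                m_t = rec_m, m_u = mm$un))
            } else {
              g$w <- g$w + w
              if (w > g$best_w) {
                g$best_w <- w
                g$cand <- list(f_t = rec_f, f_u = fm$un,
                               m_t = rec_m, m_u = mm$un)
              }
              groups[[sig]] <- g
            }
          }
        }
      }
      sigs <- ls(groups)
      if (!length(sigs))
        return(list(best = NULL, ambiguous = NA, posterior = NA_real_,
                    ok = FALSE))
      gw <- vapply(sigs, function(s) groups[[s]]$w, numeric(1))
      ord <- order(-gw, sigs)
      considered <- gw >= ambig_tol * sum(gw)
      list(best = groups[[sigs[ord[1]]]]$cand,
           ambiguous = sum(considered) > 1L,
           posterior = gw[ord[1]] / sum(gw), ok = TRUE)
  }

  gcols <- genotype_columns(locus)[-1]
  sigvec <- do.call(paste, c(lapply(trios[gcols], as.vector),
                             list(sep = ",")))
  crows <- which(trios$father_id != "0")
  rowkey <- paste(trios$family_id, trios$individual_id)
  frows <- match(paste(trios$family_id[crows], trios$father_id[crows]),
                 rowkey)
  mrows <- match(paste(trios$family_id[crows], trios$mother_id[crows]),
                 rowkey)
  fams <- trios$family_id[crows]
  tsig <- paste(sigvec[frows], sigvec[mrows], sigvec[crows], sep = "#")

  for (u in which(!duplicated(tsig))) {
    if (!is.null(trio_cache[[tsig[u]]])) next
    father <- trios[frows[u], , drop = FALSE]
    mother <- trios[mrows[u], , drop = FALSE]
    child <- trios[crows[u], , drop = FALSE]
    sol <- match_solutions(
      individual_decompositions(father, locus, lookup, cache = dcache),
      individual_decompositions(mother, locus, lookup, cache = dcache),
      individual_decompositions(child, locus, lookup, cache = dcache))
    if (!sol$ok) {
      # retry with deletion+duplication chromosome configurations
      sol <- match_solutions(
        individual_decompositions(father, locus, lookup, cache = dcache,
                                  exotic = TRUE),
        individual_decompositions(mother, locus, lookup, cache = dcache,
                                  exotic = TRUE),
        individual_decompositions(child, locus, lookup, cache = dcache,
                                  exotic = TRUE))
    }
    trio_cache[[tsig[u]]] <- sol
  }

  sols <- lapply(tsig, function(s) trio_cache[[s]])
  nfam <- length(fams)
  recs <- vector("list", 4L * nfam)
  for (i in seq_len(nfam)) {
    b <- sols[[i]]$best
    if (!is.null(b))
      recs[(4L * i - 3L):(4L * i)] <- list(b$f_t, b$f_u, b$m_t, b$m_u)
  }
  res <- data.frame(
    family_id = rep(fams, each = 4L),
    parent = rep(c("father", "father", "mother", "mother"), nfam),
    transmitted = rep(c(TRUE, FALSE, TRUE, FALSE), nfam),
    stringsAsFactors = FALSE)
  for (cnr in cnr_ids(locus))
    res[[cnr]] <- vapply(recs, function(r)
      if (is.null(r)) NA_integer_ else as.integer(r$cnr[[cnr]]), integer(1))
  for (v in names(locus$variants))
    res[[v]] <- vapply(recs, function(r)
      if (is.null(r)) NA_character_ else r$hap[[v]], character(1))
  ok <- vapply(sols, function(s) s$ok, logical(1))
  res$ambiguous <- rep(vapply(sols, function(s) as.logical(s$ambiguous),
                              logical(1)), each = 4L)
  res$posterior <- rep(vapply(sols, function(s) s$posterior, numeric(1)),
                       each = 4L)
  res$mendel_ok <- rep(ok, each = 4L)
  res$transmitted[!res$mendel_ok] <- NA
  rownames(res) <- NULL
  res
}

#' Reusable phasing cache
#'
#' Holds the haplotype-prior lookup plus decomposition and solved-trio
#' caches so that repeated \code{\link{phase_trios}} calls against the same
#' pool (e.g. simulation replicates) do not re-solve identical genotype
#' configurations.
#'
#' @param pool a \code{hap_pool}.
#' @param locus a \code{locus_definition}.
#' @return an environment with elements \code{lookup}, \code{decomp},
#'   \code{trio}.
#' @export
phase_cache <- function(pool, locus = default_locus()) {
  e <- new.env(parent = emptyenv())
  e$lookup <- build_prior_lookup(pool, locus)
  e$decomp <- new.env(parent = emptyenv())
  e$trio <- new.env(parent = emptyenv())
  e
}

#' Transmission disequilibrium test
#'
#' Allele-wise TDT over phased parental chromosomes. A parent is informative
#' for an allele when exactly one of its two chromosomes carries it;
#' T and U count transmissions and non-transmissions from informative
#' parents; Z = (T - U) / sqrt(T + U) with a two-sided normal p-value.
#' Results with informative-family count <= \code{min_informative} are
#' flagged suppressed. For a CNR marker the per-chromosome copy count
#' (0 = deletion, 1 = baseline, 2 = duplication) is the allele label; for a
#' variant marker the chromosome-level display string (e.g. "VF", "-",
#' "Stop-Stop") is.
#'
#' @param phased output of \code{\link{phase_trios}}.
#' @param marker a variant id or CNR id.
#' @param alleles labels to test (default: all observed).
#' @param min_informative suppression threshold on informative families.
#' @param include_ambiguous include families whose phase was resolved by
#'   priors.
#' @return data frame of class \code{tdt_result}: allele, freq (among
#'   parental chromosomes), families (informative), T, U, Z, p, suppressed.
#' @export
tdt <- function(phased, marker, alleles = NULL, min_informative = 10,
                include_ambiguous = TRUE) {
  ok <- phased$mendel_ok & !is.na(phased$transmitted)
  if (!include_ambiguous) ok <- ok & !phased$ambiguous
  ph <- phased[ok, , drop = FALSE]
  if (!marker %in% names(ph)) stop("unknown marker '", marker, "'")
  val <- as.character(ph[[marker]])
  if (is.null(alleles)) alleles <- sort(unique(val))
  tr <- ph$transmitted
  key <- paste(ph$family_id, ph$parent)
  t_val <- val[tr][match(unique(key), key[tr])]
  u_val <- val[!tr][match(unique(key), key[!tr])]
  fam <- ph$family_id[tr][match(unique(key), key[tr])]
  rows <- lapply(alleles, function(a) {
    has_t <- t_val == a
    has_u <- u_val == a
    informative <- xor(has_t, has_u)
    Tn <- sum(has_t & informative)
    Un <- sum(has_u & informative)
    nfam <- length(unique(fam[informative]))
    Z <- if (Tn + Un > 0) (Tn - Un) / sqrt(Tn + Un) else NA_real_
    p <- if (is.na(Z)) NA_real_ else 2 * stats::pnorm(-abs(Z))
    data.frame(marker = marker, allele = a, freq = mean(val == a),
               families = nfam, T = Tn, U = Un, Z = Z, p = p,
               suppressed = nfam <= min_informative,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("tdt_result", "data.frame")
  rownames(out) <- NULL
  out
}
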