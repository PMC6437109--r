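# Chromosome-haplotype pools: construction by iterative proportional fitting
# (IPF) against requested allele-frequency marginals and pairwise r2 targets,
# plus a CNV overlay attaching deletions/duplications to allele backgrounds.

ALLELE_SEP <- "/"

#' Build a chromosome-haplotype pool
#'
#' Constructs a frequency table over chromosome-level haplotypes of the locus
#' whose CNV-free component matches the requested per-variant allele
#' frequencies and pairwise r2 targets, with CNV chromosomes (per-CNR
#' deletion/duplication frequencies) overlaid on allele backgrounds.
#'
#' The SNP component starts from linkage equilibrium (product of marginals)
#' and is fitted by IPF: each r2 target is converted to a 2x2 joint table for
#' the allele-vs-rest collapse of its variant pair (D = sqrt(r2 pA qA pB qB),
#' positive association between the named alleles) and cell ratios are
#' applied cyclically, re-fitting the marginals after every sweep, until the
#' largest |r2 - target| is below \code{tol} or \code{max_iter} sweeps.
#'
#' Duplicated gene copies receive alleles by attachment rules: the extra
#' FCGR2C copy on a CNR1-duplicated chromosome carries the nonclassic ORF
#' with probability \code{nc_orf_dup_attach} (otherwise it duplicates the
#' base allele); extra FCGR3A/FCGR3B copies draw independently from the
#' variant's marginal; all other duplicated copies repeat the base allele.
#' Deleted genes lose their alleles.
#'
#' @param marginals named list: variant id to named numeric allele
#'   frequencies (each summing to 1 within 1e-6). \code{FCGR2C_HAP} may be
#'   given over the internal labels Stop1/Stop2/ORF/NCORF.
#' @param ld_targets data frame (or list of 5-element vectors) with columns
#'   v1, a1, v2, a2, r2: pairwise r2 for the allele-vs-rest collapses, with
#'   positive D between the named alleles.
#' @param cnr_freqs named list: CNR id to named numeric frequencies of
#'   per-chromosome copies "0"/"1"/"2". Defaults to no CNV.
#' @param seed unused (the construction is deterministic); kept so the
#'   generator API is uniform.
#' @param locus a \code{locus_definition}.
#' @param nc_orf_dup_attach probability that the extra FCGR2C copy of a
#'   CNR1 duplication carries the nonclassic ORF.
#' @param tol convergence tolerance on r2.
#' @param max_iter IPF sweep cap.
#' @param on_infeasible \code{"error"} (default): stop when a target r2
#'   exceeds the Lewontin bound implied by the marginals, reporting the
#'   feasible maximum; \code{"clamp"}: construct at the bound.
#' @return a \code{hap_pool}: data frame with per-chromosome CNR copy
#'   columns, one allele-string column per variant and a \code{freq} column
#'   summing to 1.
#' @export
build_pool <- function(marginals, ld_targets = NULL, cnr_freqs = NULL,
                       seed = NULL, locus = default_locus(),
                       nc_orf_dup_attach = 0, tol = 1e-4, max_iter = 1000,
                       on_infeasible = c("error", "clamp")) {
  on_infeasible <- match.arg(on_infeasible)
  ld_targets <- normalize_ld_targets(ld_targets)

  marg <- lapply(names(marginals), function(v) {
    m <- marginals[[v]]
    if (abs(sum(m) - 1) > 1e-6)
      stop("marginals for '", v, "' sum to ", sum(m), ", not 1")
    m / sum(m)
  })
  names(marg) <- names(marginals)
  bad <- setdiff(names(marg), names(locus$variants))
  if (length(bad)) stop("unknown variant(s): ", paste(bad, collapse = ", "))
  # variants without requested marginals are monomorphic for their first allele
  for (v in setdiff(names(locus$variants), names(marg)))
    marg[[v]] <- stats::setNames(1, variant_alleles(locus, v)[1])
  marg <- marg[names(locus$variants)]

  # linkage-equilibrium start over alleles with positive mass
  lists <- lapply(marg, function(m) names(m)[m > 0])
  grid <- expand.grid(lists, stringsAsFactors = FALSE)
  names(grid) <- names(marg)
  f <- rep(1, nrow(grid))
  for (v in names(marg)) f <- f * marg[[v]][grid[[v]]]

  pair_cells <- function(tg) {
    pA <- target_allele_freq(marg[[tg$v1]], tg$a1)
    pB <- target_allele_freq(marg[[tg$v2]], tg$a2)
    dmax <- min(pA * (1 - pB), (1 - pA) * pB)
    denom <- pA * (1 - pA) * pB * (1 - pB)
    if (denom <= 0)
      stop("monomorphic variant in LD target ", tg$v1, ":", tg$a1, " ~ ",
           tg$v2, ":", tg$a2)
    D <- sqrt(tg$r2 * denom)
    if (D > dmax + 1e-12) {
      r2max <- dmax^2 / denom
      if (on_infeasible == "error")
        stop(sprintf(
          "r2 target %.4g for %s:%s ~ %s:%s infeasible at these marginals (max %.4g)",
          tg$r2, tg$v1, tg$a1, tg$v2, tg$a2, r2max))
      D <- dmax
    }
    pAB <- pA * pB + D
    c(AB = pAB, Ab = pA - pAB, aB = pB - pAB, ab = 1 - pA - pB + pAB)
  }

  memberships <- lapply(seq_len(nrow(ld_targets)), function(i) {
    tg <- ld_targets[i, ]
    cells <- pair_cells(tg)
    pA <- cells[["AB"]] + cells[["Ab"]]
    pB <- cells[["AB"]] + cells[["aB"]]
    r2_des <- (cells[["AB"]] - pA * pB)^2 /
      (pA * (1 - pA) * pB * (1 - pB))
    list(idx = list(AB = grid[[tg$v1]] == tg$a1 & grid[[tg$v2]] == tg$a2,
                    Ab = grid[[tg$v1]] == tg$a1 & grid[[tg$v2]] != tg$a2,
                    aB = grid[[tg$v1]] != tg$a1 & grid[[tg$v2]] == tg$a2,
                    ab = grid[[tg$v1]] != tg$a1 & grid[[tg$v2]] != tg$a2),
         cells = cells, r2_des = r2_des)
  })

  achieved_r2 <- function(f, m) {
    s <- sum(f)
    pAB <- sum(f[m$idx$AB]) / s
    pA <- pAB + sum(f[m$idx$Ab]) / s
    pB <- pAB + sum(f[m$idx$aB]) / s
    (pAB - pA * pB)^2 / (pA * (1 - pA) * pB * (1 - pB))
  }

  midx <- lapply(names(marg), function(v) match(grid[[v]], names(marg[[v]])))
  names(midx) <- names(marg)

  if (length(memberships)) {
    for (iter in seq_len(max_iter)) {
      for (m in memberships) {
        for (cell in names(m$idx)) {
          cur <- sum(f[m$idx[[cell]]])
          if (cur > 0)
            f[m$idx[[cell]]] <- f[m$idx[[cell]]] * (m$cells[[cell]] / cur)
        }
      }
      # re-fit marginals disturbed by the pair steps
      for (v in names(marg)) {
        iv <- midx[[v]]
        cur <- rowsum(f, iv)
        lev <- as.integer(rownames(cur))
        scale <- as.numeric(marg[[v]][lev]) / as.numeric(cur)
        f <- f * scale[match(iv, lev)]
      }
      err <- max(vapply(memberships, function(m)
        abs(achieved_r2(f, m) - m$r2_des), numeric(1)))
      # marginals of variants refit early in the cycle drift when later
      # refits rescale correlated haplotypes; iterate until they settle too
      merr <- max(vapply(names(marg), function(v) {
        cur <- rowsum(f, midx[[v]]) / sum(f)
        max(abs(as.numeric(cur) -
                  as.numeric(marg[[v]][as.integer(rownames(cur))])))
      }, numeric(1)))
      if (err < tol && merr < 1e-9) break
    }
    if (err >= tol || merr >= 1e-9)
      warning("IPF stopped after ", max_iter,
              " sweeps with max r2 deviation ", signif(err, 3),
              " and marginal deviation ", signif(merr, 3))
  }
  f <- f / sum(f)
  keep <- f > 1e-12
  grid <- grid[keep, , drop = FALSE]
  f <- f[keep] / sum(f[keep])

  pool <- overlay_cnv(grid, f, marg, cnr_freqs, locus, nc_orf_dup_attach)
  pool <- structure(pool, class = c("hap_pool", "data.frame"),
                    locus = locus)
  attr(pool, ".dosage_matrix") <- pool_dosage_matrix(pool, locus)
  pool
}

normalize_ld_targets <- function(ld_targets) {
  if (is.null(ld_targets) || (is.data.frame(ld_targets) && !nrow(ld_targets)) ||
      (is.list(ld_targets) && !length(ld_targets)))
    return(data.frame(v1 = character(), a1 = character(), v2 = character(),
                      a2 = character(), r2 = numeric(),
                      stringsAsFactors = FALSE))
  if (!is.data.frame(ld_targets)) {
    ld_targets <- do.call(rbind, lapply(ld_targets, function(x)
      data.frame(v1 = x[[1]], a1 = x[[2]], v2 = x[[3]], a2 = x[[4]],
                 r2 = as.numeric(x[[5]]), stringsAsFactors = FALSE)))
  }
  ld_targets
}

# frequency of the allele-vs-rest collapse target; for FCGR2C_HAP with
# internal marginals the collapsed label "Stop" sums Stop1+Stop2
target_allele_freq <- function(m, allele) {
  lab <- collapse_fcgr2c(names(m))
  sum(m[lab == allele])
}

# Cross the fitted SNP table with per-CNR chromosome copy states and apply
# the allele attachment/deletion rules.
overlay_cnv <- function(grid, f, marg, cnr_freqs, locus, nc_orf_dup_attach) {
  ids <- cnr_ids(locus)
  cn_lists <- lapply(ids, function(id) {
    fr <- cnr_freqs[[id]]
    if (is.null(fr)) fr <- c(`1` = 1)
    fr <- fr[fr > 0]
    data.frame(copies = as.integer(names(fr)), p = as.numeric(fr) / sum(fr))
  })
  names(cn_lists) <- ids
  states <- expand.grid(lapply(cn_lists, function(d) seq_len(nrow(d))))
  out <- vector("list", nrow(states))
  for (s in seq_len(nrow(states))) {
    cn <- vapply(ids, function(id) cn_lists[[id]]$copies[states[[id]][s]],
                 integer(1))
    ps <- prod(vapply(ids, function(id) cn_lists[[id]]$p[states[[id]][s]],
                      numeric(1)))
    # skip combinations whose overlapping deletions would leave a gene with
    # negative copy number (biologically impossible chromosome)
    kk <- vapply(locus$genes, function(g) chrom_gene_copies(cn, g, locus),
                 integer(1))
    if (any(kk < 0)) next
    blocks <- list(list(g = grid, w = f * ps))
    for (v in names(locus$variants)) {
      gene <- variant_gene(locus, v)
      k <- chrom_gene_copies(cn, gene, locus)
      if (k == 1L) next
      new_blocks <- list()
      for (b in blocks) {
        if (k == 0L) {
          b$g[[v]] <- ""
          new_blocks <- c(new_blocks, list(b))
          next
        }
        # one extra copy per duplicated CNR containing the gene
        extra_cnrs <- rep(ids, pmax(0L, cn - 1L))
        extra_cnrs <- extra_cnrs[vapply(extra_cnrs, function(id)
          gene %in% locus$cnrs[[id]]$genes, logical(1))]
        opts_per_extra <- lapply(extra_cnrs, function(id)
          extra_copy_options(v, gene, id, marg, nc_orf_dup_attach))
        combos <- expand.grid(lapply(opts_per_extra, function(o)
          seq_len(nrow(o))))
        for (ci in seq_len(max(1L, nrow(combos)))) {
          bb <- b
          w_extra <- 1
          add <- character(0)
          if (length(opts_per_extra)) {
            for (j in seq_along(opts_per_extra)) {
              o <- opts_per_extra[[j]][combos[ci, j], ]
              add <- c(add, o$allele)
              w_extra <- w_extra * o$p
            }
          }
          bb$w <- bb$w * w_extra
          base_col <- bb$g[[v]]
          parts <- list(base_col)
          for (a in add)
            parts <- c(parts, list(if (a == ".base") base_col
                                   else rep(a, length(base_col))))
          bb$g[[v]] <- do.call(paste, c(parts, sep = ALLELE_SEP))
          new_blocks <- c(new_blocks, list(bb))
        }
      }
      blocks <- new_blocks
    }
    df <- do.call(rbind, lapply(blocks, function(b) {
      d <- b$g
      for (j in seq_along(ids)) d[[ids[j]]] <- cn[j]
      d$freq <- b$w
      d
    }))
    out[[s]] <- df
  }
  pool <- do.call(rbind, out)
  pool <- pool[, c(ids, names(locus$variants), "freq")]
  # canonicalize allele strings (sorted within chromosome) and aggregate
  for (v in names(locus$variants))
    pool[[v]] <- vapply(strsplit(pool[[v]], ALLELE_SEP, fixed = TRUE),
                        function(a) paste(sort(a), collapse = ALLELE_SEP),
                        character(1))
  key <- do.call(paste, c(pool[, c(ids, names(locus$variants))], sep = "\r"))
  freq <- tapply(pool$freq, key, sum)
  first <- !duplicated(key)
  agg <- pool[first, , drop = FALSE]
  agg$freq <- as.numeric(freq[key[first]])
  agg <- agg[agg$freq > 1e-12, , drop = FALSE]
  agg$freq <- agg$freq / sum(agg$freq)
  rownames(agg) <- NULL
  agg
}

# allele options (with probabilities) for one extra gene copy arising from a
# duplication of `cnr_id`
extra_copy_options <- function(variant, gene, cnr_id, marg, nc_orf_dup_attach) {
  if (variant == "FCGR2C_HAP" && cnr_id == "CNR1" && nc_orf_dup_attach > 0) {
    opts <- data.frame(allele = c("NCORF", ".base"),
                       p = c(nc_orf_dup_attach, 1 - nc_orf_dup_attach),
                       stringsAsFactors = FALSE)
    return(opts[opts$p > 0, , drop = FALSE])
  }
  if (gene %in% c("FCGR3A", "FCGR3B") && variant %in% names(marg)) {
    m <- marg[[variant]]
    m <- m[m > 0]
    return(data.frame(allele = names(m), p = as.numeric(m),
                      stringsAsFactors = FALSE))
  }
  data.frame(allele = ".base", p = 1, stringsAsFactors = FALSE)
}

#' Default population pools
#'
#' Builds the packaged reference pool for one of the three default
#' populations (European, Chinese, African). r2 targets that sit above the
#' Lewontin bound implied by the (rounded) marginals are constructed at the
#' bound.
#'
#' @param population one of "EUR", "CHN", "AFR".
#' @param locus a \code{locus_definition}.
#' @param ... passed to \code{\link{build_pool}}.
#' @return a \code{hap_pool}.
#' @export
population_pool <- function(population = c("EUR", "CHN", "AFR"),
                            locus = default_locus(), ...) {
  population <- match.arg(population)
  key <- paste0("pool_", population)
  if (!is.null(.locus_cache[[key]])) return(.locus_cache[[key]])
  cfg <- population_defaults(population)
  pool <- build_pool(cfg$marginals, cfg$ld_targets, cfg$cnr_chrom_freqs,
                     locus = locus,
                     nc_orf_dup_attach = cfg$nc_orf_dup_attach,
                     on_infeasible = "clamp", ...)
  .locus_cache[[key]] <- pool
  pool
}

#' Packaged population parameter sets
#'
#' @param population one of "EUR", "CHN", "AFR".
#' @return list with elements \code{marginals}, \code{ld_targets},
#'   \code{cnr_chrom_freqs}, \code{nc_orf_dup_attach}.
#' @export
population_defaults <- function(population = c("EUR", "CHN", "AFR")) {
  population <- match.arg(population)
  cfgs <- yaml::read_yaml(system.file("extdata", "populations.yaml",
                                      package = "fcgrhap"))
  cfg <- cfgs[[population]]
  cfg$marginals <- lapply(cfg$marginals, function(m)
    stats::setNames(as.numeric(unlist(m)), names(m)))
  cfg$cnr_chrom_freqs <- lapply(cfg$cnr_chrom_freqs, function(m)
    stats::setNames(as.numeric(unlist(m)), names(m)))
  cfg$ld_targets <- normalize_ld_targets(cfg$ld_targets)
  cfg
}

#' @export
print.hap_pool <- function(x, ...) {
  cat("<hap_pool> ", nrow(x), " chromosome haplotypes\n", sep = "")
  ord <- order(-x$freq)
  print.data.frame(utils::head(x[ord, ], 10), digits = 4)
  if (nrow(x) > 10) cat("... and", nrow(x) - 10, "more rows\n")
  invisible(x)
}

pool_locus <- function(pool) attr(pool, "locus") %||% default_locus()

# number of copies of `gene` on each pool chromosome
pool_gene_copies <- function(pool, gene, locus = pool_locus(pool)) {
  ids <- cnrs_containing(locus, gene)
  if (length(ids) == 0L) return(rep.int(1L, nrow(pool)))
  1L + rowSums(as.matrix(pool[, ids, drop = FALSE])) - length(ids)
}

# per-chromosome dosage matrix over the genotype dosage columns (collapsed
# FCGR2C labels)
pool_dosage_matrix <- function(pool, locus = pool_locus(pool)) {
  cols <- dosage_columns(locus)
  M <- matrix(0L, nrow(pool), length(cols), dimnames = list(NULL, cols))
  for (v in names(locus$variants)) {
    alle <- variant_alleles(locus, v)
    vcols <- variant_columns(locus, v)
    parts <- strsplit(pool[[v]], ALLELE_SEP, fixed = TRUE)
    for (j in seq_along(alle)) {
      M[, vcols[j]] <- vapply(parts, function(a)
        sum(collapse_fcgr2c(a) == alle[j]), integer(1))
    }
  }
  M
}

#' Marginal allele frequencies of a pool
#'
#' Chromosome-level allele frequencies for one variant, computed either on
#' the CNV-free component of the pool (default; the conditioning under which
#' the pool's marginals and LD targets are defined) or dosage-weighted over
#' all chromosomes.
#'
#' @param pool a \code{hap_pool}.
#' @param variant variant id.
#' @param cnv_free restrict to chromosomes with all CNRs at baseline.
#' @param internal keep the internal FCGR2C labels.
#' @return named numeric frequencies summing to 1.
#' @export
pool_marginals <- function(pool, variant, cnv_free = TRUE, internal = FALSE) {
  locus <- pool_locus(pool)
  keep <- if (cnv_free) baseline_rows(pool, locus) else rep(TRUE, nrow(pool))
  parts <- strsplit(pool[[variant]][keep], ALLELE_SEP, fixed = TRUE)
  w <- pool$freq[keep]
  lab <- unlist(parts, use.names = FALSE)
  if (!internal) lab <- collapse_fcgr2c(lab)
  wts <- rep(w, lengths(parts))
  tot <- tapply(wts, lab, sum)
  out <- as.numeric(tot) / sum(wts)
  stats::setNames(out, names(tot))
}

baseline_rows <- function(pool, locus = pool_locus(pool)) {
  ids <- cnr_ids(locus)
  rowSums(as.matrix(pool[, ids, drop = FALSE]) == 1L) == length(ids)
}

#' Pairwise r2 between two allele collapses of a pool
#'
#' Computed on the CNV-free component (one gene copy per chromosome, so the
#' allele-vs-rest collapse is well defined).
#'
#' @param pool a \code{hap_pool}.
#' @param v1,a1,v2,a2 variant ids and focal alleles.
#' @return r2 of the 2x2 collapse.
#' @export
pool_r2 <- function(pool, v1, a1, v2, a2) {
  locus <- pool_locus(pool)
  keep <- baseline_rows(pool, locus)
  w <- pool$freq[keep] / sum(pool$freq[keep])
  x1 <- collapse_fcgr2c(pool[[v1]][keep]) == a1
  x2 <- collapse_fcgr2c(pool[[v2]][keep]) == a2
  pA <- sum(w[x1]); pB <- sum(w[x2]); pAB <- sum(w[x1 & x2])
  (pAB - pA * pB)^2 / (pA * (1 - pA) * pB * (1 - pB))
}
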