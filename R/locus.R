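#' @keywords internal
"_PACKAGE"

# Internal FCGR2C haplotype labels: the two Stop backgrounds differ in splice
# status (intact vs mutant) and are distinguishable only from raw dosage data;
# everywhere outside the MLPA caller they are collapsed to "Stop".
.fcgr2c_internal <- c("Stop1", "Stop2", "ORF", "NCORF")

#' Collapse internal FCGR2C haplotype labels
#'
#' Maps the two Stop backgrounds (intact / splice-mutant) onto the single
#' reported "Stop" label; classic and nonclassic ORF are unchanged.
#'
#' @param x character vector of FCGR2C haplotype labels.
#' @return character vector over \code{c("Stop", "ORF", "NCORF")}.
#' @export
collapse_fcgr2c <- function(x) {
  x[x %in% c("Stop1", "Stop2")] <- "Stop"
  x
}

#' Read a locus definition
#'
#' Loads a structured-text (YAML) description of a gene cluster: ordered gene
#' list, copy-number-variable regions (CNRs, blocks of genes deleted or
#' duplicated as a unit) and variant systems with their allele labels.
#'
#' @param path path to a YAML locus definition; defaults to the packaged
#'   FCGR2/3 definition.
#' @return an object of class \code{locus_definition}.
#' @export
read_locus <- function(path = system.file("extdata", "fcgr23_locus.yaml",
                                          package = "fcgrhap")) {
  raw <- yaml::read_yaml(path)
  genes <- as.character(raw$genes)
  if (anyDuplicated(genes)) stop("duplicate gene names in locus definition")
  cnrs <- lapply(raw$cnrs, function(cn) {
    list(genes = as.character(cn$genes),
         copy_range = as.integer(cn$copy_range))
  })
  for (id in names(cnrs)) {
    cn <- cnrs[[id]]
    if (length(cn$genes) == 0L) stop("CNR '", id, "' contains no genes")
    if (!all(cn$genes %in% genes))
      stop("CNR '", id, "' names genes absent from the locus")
    if (cn$copy_range[1] < 0L) stop("CNR '", id, "' has negative copy range")
  }
  variants <- lapply(raw$variants, function(v) {
    list(gene = as.character(v$gene), alleles = as.character(v$alleles))
  })
  for (id in names(variants)) {
    v <- variants[[id]]
    if (!v$gene %in% genes)
      stop("variant '", id, "' is on gene '", v$gene, "' absent from the locus")
    if (length(v$alleles) < 2L) stop("variant '", id, "' needs >= 2 alleles")
    if (anyDuplicated(v$alleles)) stop("variant '", id, "' has duplicate alleles")
  }
  structure(list(genes = genes, cnrs = cnrs, variants = variants),
            class = "locus_definition")
}

.locus_cache <- new.env(parent = emptyenv())

#' Default FCGR2/3 locus definition
#'
#' @return the packaged FCGR2/3 \code{locus_definition} (cached).
#' @export
default_locus <- function() {
  if (is.null(.locus_cache$locus)) .locus_cache$locus <- read_locus()
  .locus_cache$locus
}

#' @export
print.locus_definition <- function(x, ...) {
  cat("<locus_definition> ", length(x$genes), " genes, ",
      length(x$cnrs), " CNRs, ", length(x$variants), " variant systems\n",
      sep = "")
  cat("  genes:", paste(x$genes, collapse = ", "), "\n")
  for (id in names(x$cnrs))
    cat("  ", id, ": ", paste(x$cnrs[[id]]$genes, collapse = "+"), "\n", sep = "")
  invisible(x)
}

cnr_ids <- function(locus) names(locus$cnrs)

# CNRs whose gene set contains `gene`
cnrs_containing <- function(locus, gene) {
  ids <- names(locus$cnrs)
  ids[vapply(locus$cnrs, function(cn) gene %in% cn$genes, logical(1))]
}

variant_gene <- function(locus, variant) locus$variants[[variant]]$gene
variant_alleles <- function(locus, variant) locus$variants[[variant]]$alleles

# Dosage column names for a variant: "<gene>_<allele>"
variant_columns <- function(locus, variant) {
  paste(variant_gene(locus, variant), variant_alleles(locus, variant), sep = "_")
}

# All dosage columns of a genotype frame, in locus order
dosage_columns <- function(locus) {
  unlist(lapply(names(locus$variants), function(v) variant_columns(locus, v)),
         use.names = FALSE)
}

genotype_columns <- function(locus) {
  c("individual_id", cnr_ids(locus), dosage_columns(locus))
}

#' Gene copy number of individuals
#'
#' Total copy number of a gene given per-individual CNR copy numbers:
#' \code{2 + sum over CNRs containing the gene of (CNR copies - 2)}. Genes in
#' no CNR always have 2 copies.
#'
#' @param genotypes genotype data frame (one row per individual) with CNR
#'   columns.
#' @param gene gene name.
#' @param locus a \code{locus_definition}.
#' @return integer vector of per-individual copy numbers.
#' @export
gene_copy_number <- function(genotypes, gene, locus = default_locus()) {
  if (!gene %in% locus$genes) stop("unknown gene '", gene, "'")
  copies <- rep.int(2L, nrow(genotypes))
  for (cnr in cnrs_containing(locus, gene))
    copies <- copies + as.integer(genotypes[[cnr]]) - 2L
  copies
}

# Per-chromosome copy count of `gene` given a named per-CNR copy vector
# (baseline chromosome has 1 copy of every CNR).
chrom_gene_copies <- function(cnr, gene, locus = default_locus()) {
  ids <- cnrs_containing(locus, gene)
  if (length(ids) == 0L) return(1L)
  1L + sum(as.integer(cnr[ids]) - 1L)
}

#' Construct a chromosome-level haplotype
#'
#' One parental chromosome of the locus: per-CNR copy count (0, 1 or 2; 1 is
#' the no-CNV baseline) and, for each variant system, the allele carried by
#' each copy of its gene on this chromosome.
#'
#' @param cnr named integer vector of per-CNR copies (missing CNRs default
#'   to 1).
#' @param alleles named list, one entry per variant id, each a character
#'   vector with one allele label per gene copy on this chromosome (empty if
#'   the gene is deleted).
#' @param locus a \code{locus_definition}.
#' @param internal if \code{TRUE}, FCGR2C haplotype labels may use the
#'   internal Stop1/Stop2 distinction.
#' @return an object of class \code{chrom_haplotype}.
#' @export
chrom_haplotype <- function(cnr = NULL, alleles = list(),
                            locus = default_locus(), internal = FALSE) {
  full <- stats::setNames(rep.int(1L, length(locus$cnrs)), cnr_ids(locus))
  if (!is.null(cnr)) {
    bad <- setdiff(names(cnr), names(full))
    if (length(bad)) stop("unknown CNR(s): ", paste(bad, collapse = ", "))
    full[names(cnr)] <- as.integer(cnr)
  }
  if (any(full < 0L | full > 2L))
    stop("per-chromosome CNR copies must be 0, 1 or 2")
  out <- list(cnr = full, alleles = vector("list", length(locus$variants)))
  names(out$alleles) <- names(locus$variants)
  for (v in names(locus$variants)) {
    g <- variant_gene(locus, v)
    k <- chrom_gene_copies(full, g, locus)
    a <- as.character(alleles[[v]] %||% character(0))
    if (length(a) != k)
      stop("variant '", v, "': ", length(a), " allele(s) supplied but gene '",
           g, "' has ", k, " copies on this chromosome")
    ok <- variant_alleles(locus, v)
    if (internal && v == "FCGR2C_HAP") ok <- union(ok, .fcgr2c_internal)
    if (!all(a %in% ok))
      stop("variant '", v, "': unknown allele label(s) ",
           paste(setdiff(a, ok), collapse = ", "))
    out$alleles[[v]] <- a
  }
  structure(out, class = "chrom_haplotype")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Display form of a chromosome haplotype at one gene
#'
#' Uses "-" for a deleted gene, plain concatenation for single-character
#' allele labels (e.g. "VF") and hyphen-joined labels otherwise (e.g.
#' "NA1-NA2", "Stop-Stop"). Alleles are sorted so the form is canonical.
#'
#' @param hap a \code{chrom_haplotype}, or a character vector of allele labels.
#' @param variant variant id (when \code{hap} is a \code{chrom_haplotype}).
#' @return a single string.
#' @export
hap_string <- function(hap, variant = NULL) {
  a <- if (inherits(hap, "chrom_haplotype")) hap$alleles[[variant]] else hap
  a <- sort(collapse_fcgr2c(as.character(a[nzchar(a)])))
  if (length(a) == 0L) return("-")
  if (all(nchar(a) == 1L)) paste(a, collapse = "") else paste(a, collapse = "-")
}

#' Combine two chromosome haplotypes into an unphased genotype
#'
#' Element-wise sum of CNR copies and allele dosages; the diplotype to
#' genotype projection.
#'
#' @param h1,h2 \code{chrom_haplotype} objects on the same locus.
#' @param locus a \code{locus_definition}.
#' @param id individual id for the output row.
#' @return a one-row genotype data frame.
#' @export
combine_chromosomes <- function(h1, h2, locus = default_locus(),
                                id = "ind1") {
  stopifnot(inherits(h1, "chrom_haplotype"), inherits(h2, "chrom_haplotype"))
  if (!identical(names(h1$cnr), names(h2$cnr)) ||
      !identical(names(h1$alleles), names(h2$alleles)))
    stop("haplotypes are defined on different loci")
  row <- as.list(h1$cnr + h2$cnr)
  for (v in names(locus$variants)) {
    alle <- variant_alleles(locus, v)
    pooled <- collapse_fcgr2c(c(h1$alleles[[v]], h2$alleles[[v]]))
    cnt <- table(factor(pooled, levels = alle))
    row[variant_columns(locus, v)] <- as.integer(cnt)
  }
  out <- cbind(data.frame(individual_id = id, stringsAsFactors = FALSE),
               as.data.frame(row, check.names = FALSE, optional = TRUE))
  names(out) <- c("individual_id", names(h1$cnr), dosage_columns(locus))
  validate_genotypes(out, locus)
  out
}

#' Validate genotype invariants
#'
#' Checks that, for every variant, allele dosages sum to the copy number of
#' its gene, and that all dosages and CNR copies are non-negative integers.
#'
#' @param genotypes genotype data frame.
#' @param locus a \code{locus_definition}.
#' @return the input, invisibly; errors name the first offending individual.
#' @export
validate_genotypes <- function(genotypes, locus = default_locus()) {
  need <- genotype_columns(locus)
  miss <- setdiff(need, names(genotypes))
  if (length(miss))
    stop("genotype frame lacks column(s): ", paste(miss, collapse = ", "))
  for (cnr in cnr_ids(locus)) {
    x <- genotypes[[cnr]]
    if (any(x < 0 | x != round(x)))
      stop("non-integer or negative ", cnr, " copies (individual ",
           genotypes$individual_id[which(x < 0 | x != round(x))[1]], ")")
  }
  for (v in names(locus$variants)) {
    cols <- variant_columns(locus, v)
    d <- as.matrix(genotypes[cols])
    if (any(d < 0))
      stop("negative dosage for ", v, " (individual ",
           genotypes$individual_id[which(rowSums(d < 0) > 0)[1]], ")")
    cn <- gene_copy_number(genotypes, variant_gene(locus, v), locus)
    bad <- which(rowSums(d) != cn)
    if (length(bad))
      stop("dosages for ", v, " do not sum to the ", variant_gene(locus, v),
           " copy number (individual ", genotypes$individual_id[bad[1]], ")")
  }
  invisible(genotypes)
}
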