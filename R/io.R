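# Tab-separated dialects: genotype tables, PED-like trio files, probe-ratio
# tables.

#' Write / read a genotype table
#'
#' Columns: individual_id, one column per CNR (total copies), then one
#' integer dosage column per variant allele named \code{<gene>_<allele>}.
#'
#' @param genotypes genotype data frame.
#' @param path file path.
#' @param locus a \code{locus_definition}.
#' @return \code{read_genotypes} returns the validated genotype frame.
#' @export
write_genotypes <- function(genotypes, path, locus = default_locus()) {
  utils::write.table(genotypes[genotype_columns(locus)], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path, locus = default_locus()) {
  g <- utils::read.delim(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  validate_genotypes(g, locus)
  g
}

#' Write / read a PED-like trio table
#'
#' Columns family_id, individual_id, father_id, mother_id, affected
#' (1 = unaffected, 2 = affected), then the genotype-table columns.
#'
#' @param trios trio data frame (three rows per family).
#' @param path file path.
#' @param locus a \code{locus_definition}.
#' @return \code{read_trios} returns the trio frame.
#' @export
write_trios <- function(trios, path, locus = default_locus()) {
  cols <- c("family_id", "individual_id", "father_id", "mother_id",
            "affected", genotype_columns(locus)[-1])
  utils::write.table(trios[cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_trios
#' @export
read_trios <- function(path, locus = default_locus()) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = c(family_id = "character",
                                   individual_id = "character",
                                   father_id = "character",
                                   mother_id = "character"))
}

#' Write / read a probe-ratio table
#'
#' Columns individual_id, probe_id, target, ratio (normalized;
#' 1.0 = two copies).
#'
#' @param probes probe-ratio data frame.
#' @param path file path.
#' @return \code{read_probe_ratios} returns the probe frame.
#' @export
write_probe_ratios <- function(probes, path) {
  utils::write.table(probes, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_probe_ratios
#' @export
read_probe_ratios <- function(path) {
  utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                    colClasses = c(individual_id = "character"))
}
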