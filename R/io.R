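# Plain-text writers and readers for the pipeline's tables. All internal
# coordinates are 0-based half-open; the VCF writer converts to the
# 1-based convention of that format.

#' Write / read a genotype dosage TSV
#'
#' One row per variant (`variant_id`, `chrom`, `pos`, `maf`, then one
#' dosage column per sample).
#' @param genotypes A [genotype_matrix()].
#' @param path Output file.
#' @export
write_genotypes_tsv <- function(genotypes, path) {
  d <- cbind(genotypes$annot,
             as.data.frame(t(genotypes$dosages), check.names = FALSE))
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_genotypes_tsv
#' @export
read_genotypes_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  ann_cols <- c("variant_id", "chrom", "pos", "maf")
  annot <- d[, ann_cols]
  dos <- t(as.matrix(d[, setdiff(names(d), ann_cols), drop = FALSE]))
  colnames(dos) <- annot$variant_id
  genotype_matrix(dos, annot)
}

#' Write a minimal VCF of dosages
#'
#' Hard-called genotypes (`0/0`, `0/1`, `1/1`) with placeholder alleles;
#' positions converted to the 1-based VCF convention.
#' @param genotypes A [genotype_matrix()].
#' @param path Output file (uncompressed `.vcf`).
#' @export
write_vcf_minimal <- function(genotypes, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                       "FILTER", "INFO", "FORMAT",
                       rownames(genotypes$dosages)), collapse = "\t")),
             con)
  gt <- c("0/0", "0/1", "1/1")
  for (j in seq_len(ncol(genotypes$dosages))) {
    a <- genotypes$annot[j, ]
    writeLines(paste(c(a$chrom, a$pos + 1L, a$variant_id, "A", "G", ".",
                       "PASS", ".", "GT",
                       gt[round(genotypes$dosages[, j]) + 1L]),
                     collapse = "\t"), con)
  }
  invisible(path)
}

#' Write / read a phenotype TSV with feature annotation columns
#' @param fm A [feature_matrix()].
#' @param path Output file.
#' @export
write_phenotypes_tsv <- function(fm, path) {
  d <- cbind(fm$annot, as.data.frame(t(fm$values), check.names = FALSE))
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_phenotypes_tsv
#' @export
read_phenotypes_tsv <- function(path) {
  d <- utils::read.delim(path, check.names = FALSE)
  ann_cols <- intersect(c("feature_id", "chrom", "start", "end", "tss",
                          "kind", "near_gene"), names(d))
  annot <- d[, ann_cols]
  v <- t(as.matrix(d[, setdiff(names(d), ann_cols), drop = FALSE]))
  colnames(v) <- annot$feature_id
  feature_matrix(v, annot)
}

#' Write a GWAS summary TSV
#'
#' Columns `CHR, POS, ID, REF, ALT, BETA, SE, Z, P, N, MAF` (positions
#' 1-based as in conventional summary-statistic releases).
#' @param summary A `gwas_summary` data frame from [simulate_gwas()].
#' @param path Output file.
#' @export
write_gwas_tsv <- function(summary, path) {
  d <- data.frame(CHR = summary$chrom, POS = summary$pos + 1L,
                  ID = summary$variant_id, REF = "A", ALT = "G",
                  BETA = summary$beta, SE = summary$se, Z = summary$z,
                  P = summary$p, N = summary$n, MAF = summary$maf)
  utils::write.table(d, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Write / read interaction calls as a BEDPE-like TSV
#' @param calls Interaction-call data frame ([interaction_calls()]).
#' @param path Output file.
#' @export
write_interactions_tsv <- function(calls, path) {
  utils::write.table(calls, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_interactions_tsv
#' @export
read_interactions_tsv <- function(path) {
  interaction_calls(utils::read.delim(path, check.names = FALSE))
}
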