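# Lightweight S3 containers for the two data shapes the pipeline moves
# around: sample x variant dosages and sample x feature phenotypes.

#' Construct a genotype matrix
#'
#' @param dosages Numeric sample x variant matrix of allele dosages in
#'   `[0, 2]`; row names are sample ids, column names variant ids.
#' @param annot Data frame with one row per variant and columns
#'   `variant_id`, `chrom`, `pos` (0-based), `maf`.
#' @return An object of class `genotype_matrix`: a list with elements
#'   `dosages` and `annot`.
#' @export
genotype_matrix <- function(dosages, annot) {
  dosages <- as.matrix(dosages)
  stopifnot(is.data.frame(annot),
            all(c("variant_id", "chrom", "pos", "maf") %in% names(annot)))
  if (ncol(dosages) != nrow(annot))
    stopf("dosage columns (%d) != annotation rows (%d)",
          ncol(dosages), nrow(annot))
  if (is.null(colnames(dosages))) colnames(dosages) <- annot$variant_id
  if (anyDuplicated(annot$variant_id))
    stopf("duplicated variant ids")
  ord <- order(annot$chrom, annot$pos)
  structure(list(dosages = dosages[, ord, drop = FALSE],
                 annot = annot[ord, , drop = FALSE]),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat(sprintf("genotype_matrix: %d samples x %d variants on %s\n",
              nrow(x$dosages), ncol(x$dosages),
              paste(unique(x$annot$chrom), collapse = ",")))
  invisible(x)
}

#' Construct a feature matrix
#'
#' Holds a phenotype matrix for genes (TSS-anchored) or peaks
#' (interval-anchored). Coordinates are 0-based half-open.
#'
#' @param values Numeric sample x feature matrix.
#' @param annot Data frame with columns `feature_id`, `chrom`, `start`,
#'   `end`, and for genes a `tss` column; optional `kind` column
#'   (`"gene"` or `"peak"`).
#' @return An object of class `feature_matrix`.
#' @export
feature_matrix <- function(values, annot) {
  values <- as.matrix(values)
  stopifnot(is.data.frame(annot),
            all(c("feature_id", "chrom", "start", "end") %in% names(annot)))
  if (ncol(values) != nrow(annot))
    stopf("value columns (%d) != annotation rows (%d)",
          ncol(values), nrow(annot))
  if (is.null(rownames(values)))
    stopf("feature_matrix requires sample ids as row names")
  if (any(annot$end <= annot$start))
    stopf("feature intervals must satisfy end > start (half-open)")
  if (any(annot$start < 0)) stopf("feature coordinates must be non-negative")
  if ("tss" %in% names(annot)) {
    bad <- !is.na(annot$tss) &
      (annot$tss < annot$start | annot$tss >= annot$end)
    if (any(bad))
      stopf("TSS outside gene span for: %s",
            paste(utils::head(annot$feature_id[bad], 5), collapse = ", "))
  }
  if (is.null(colnames(values))) colnames(values) <- annot$feature_id
  structure(list(values = values, annot = annot), class = "feature_matrix")
}

#' @export
print.feature_matrix <- function(x, ...) {
  kind <- if ("kind" %in% names(x$annot))
    paste(unique(x$annot$kind), collapse = "/") else "feature"
  cat(sprintf("feature_matrix: %d samples x %d %ss\n",
              nrow(x$values), ncol(x$values), kind))
  invisible(x)
}

#' Subset a feature matrix by feature ids
#' @param fm A [feature_matrix()].
#' @param ids Character vector of feature ids to keep.
#' @return A `feature_matrix` restricted to `ids`, in their stored order.
#' @export
subset_features <- function(fm, ids) {
  keep <- fm$annot$feature_id %in% ids
  feature_matrix(fm$values[, keep, drop = FALSE],
                 fm$annot[keep, , drop = FALSE])
}
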