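# Cis / trans window definitions. Coordinates are 0-based; gene windows
# are closed intervals around the TSS, peak windows extend the half-open
# peak interval by 10 kb on each side.

#' Cis window of a feature
#'
#' Genes: variants within 1 Mb of the transcription start site (closed
#' interval). Peaks: variants within 10 kb of either end of the peak
#' interval (half-open). Lower bounds are clipped at 0.
#'
#' @param feature One-row feature annotation (needs `chrom` and `tss` for
#'   genes, `start`/`end` for peaks).
#' @param kind `"gene"` or `"peak"`.
#' @param gene_flank Cis distance from the TSS for genes (bp).
#' @param peak_flank Cis distance beyond each peak end (bp).
#' @return List with `chrom`, `start`, `end`, and `closed` (`TRUE` for
#'   gene windows, `FALSE` for half-open peak windows).
#' @export
cis_window <- function(feature, kind = c("gene", "peak"),
                       gene_flank = 1000000L, peak_flank = 10000L) {
  kind <- match.arg(kind)
  if (kind == "gene") {
    tss <- feature$tss
    if (is.null(tss) || is.na(tss)) stopf("gene feature lacks a TSS")
    list(chrom = feature$chrom, start = max(0L, tss - gene_flank),
         end = tss + gene_flank, closed = TRUE)
  } else {
    list(chrom = feature$chrom, start = max(0L, feature$start - peak_flank),
         end = feature$end + peak_flank, closed = FALSE)
  }
}

#' Variant ids of a genotype panel inside a window
#'
#' @param genotypes A [genotype_matrix()].
#' @param window A window as returned by [cis_window()].
#' @return Character vector of variant ids, in position order.
#' @export
window_variants <- function(genotypes, window) {
  va <- genotypes$annot
  hit <- va$chrom == window$chrom & va$pos >= window$start &
    (if (isTRUE(window$closed)) va$pos <= window$end else va$pos < window$end)
  va$variant_id[hit]
}

#' Trans variant set for a feature
#'
#' Variants on another chromosome, or on the same chromosome strictly
#' more than `min_distance` from the feature anchor (TSS for genes, the
#' nearest interval edge for peaks).
#'
#' @param feature One-row feature annotation.
#' @param variants Variant annotation data frame (`variant_id`, `chrom`,
#'   `pos`).
#' @param kind `"gene"` or `"peak"`.
#' @param min_distance Distance beyond which a pair counts as trans (bp);
#'   a pair at exactly this distance is cis.
#' @return Character vector of trans variant ids.
#' @export
trans_pairs <- function(feature, variants, kind = c("gene", "peak"),
                        min_distance = 5000000L) {
  kind <- match.arg(kind)
  other <- variants$chrom != feature$chrom
  if (kind == "gene") {
    d <- abs(variants$pos - feature$tss)
  } else {
    d <- pmax(0L, feature$start - variants$pos,
              variants$pos - (feature$end - 1L))
  }
  variants$variant_id[other | (!other & d > min_distance)]
}
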