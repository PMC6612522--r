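# LD-based linking of molecular QTLs to each other and to GWAS leads,
# promoter-capture interaction merging, peak-to-gene assignment, and the
# locus-anatomy statistics built on them.

#' LD between two variants
#'
#' Squared Pearson correlation of dosage vectors in a reference
#' genotype panel (unphased, dosage-based r^2). Symmetric and invariant
#' to allele flips.
#'
#' @param genotypes Reference [genotype_matrix()].
#' @param v1,v2 Variant ids.
#' @return r^2 in `[0, 1]`.
#' @export
ld_r2 <- function(genotypes, v1, v2) {
  for (v in c(v1, v2))
    if (!v %in% colnames(genotypes$dosages))
      stopf("variant '%s' not in the reference panel", v)
  a <- genotypes$dosages[, v1]
  b <- genotypes$dosages[, v2]
  if (sd(a) == 0 || sd(b) == 0)
    stopf("LD undefined: monomorphic variant in the reference panel")
  min(cor(a, b)^2, 1)
}

# r^2 of one variant against many (columns of a standardized panel).
ld_r2_vector <- function(g_std, v, others) {
  drop(crossprod(g_std[, v], g_std[, others, drop = FALSE]) /
         (nrow(g_std) - 1))^2
}

# Peak-interval to TSS distance: 0 when the TSS lies inside the
# half-open interval, otherwise the gap to the nearest edge.
peak_tss_distance <- function(start, end, tss) {
  pmax(0L, start - tss, tss - (end - 1L))
}

#' Putatively co-regulated gene-peak pairs
#'
#' For each gene with a significant lead eQTL, tests every
#' significant-hQTL peak within `window` of its TSS: a pair is reported
#' when `r^2` between the lead eQTL and lead hQTL exceeds `r2_min`.
#' Pairs in the MHC region are excluded.
#'
#' @param eqtl_leads Data frame `feature_id`, `lead_variant` for genes.
#' @param hqtl_leads Data frame `feature_id`, `lead_variant` for peaks.
#' @param genes Gene annotation (`feature_id`, `chrom`, `tss`).
#' @param peaks Peak annotation (`feature_id`, `chrom`, `start`, `end`).
#' @param reference_genotypes Reference [genotype_matrix()] for LD.
#' @param r2_min LD threshold (strict `>`).
#' @param window Maximum peak-to-TSS distance (bp).
#' @param mhc Exclusion interval (list `chrom`, `start`, `end`) or
#'   `NULL`; defaults to [mhc_interval()].
#' @return Data frame of class pairs: `gene_id`, `peak_id`,
#'   `lead_eqtl`, `lead_hqtl`, `r2`, `distance`, `n_closer_genes`.
#' @export
coregulated_pairs <- function(eqtl_leads, hqtl_leads, genes, peaks,
                              reference_genotypes, r2_min = 0.8,
                              window = 1000000L, mhc = mhc_interval()) {
  g_std <- standardize_cols(reference_genotypes$dosages)
  out <- list()
  for (i in seq_len(nrow(eqtl_leads))) {
    gid <- eqtl_leads$feature_id[i]
    ga <- genes[genes$feature_id == gid, ]
    if (!nrow(ga)) next
    for (j in seq_len(nrow(hqtl_leads))) {
      pid <- hqtl_leads$feature_id[j]
      pa <- peaks[peaks$feature_id == pid, ]
      if (!nrow(pa) || pa$chrom != ga$chrom) next
      d <- peak_tss_distance(pa$start, pa$end, ga$tss)
      if (d > window) next
      ve <- eqtl_leads$lead_variant[i]
      vh <- hqtl_leads$lead_variant[j]
      if (!all(c(ve, vh) %in% colnames(g_std))) next
      if (anyNA(g_std[1, c(ve, vh)])) next
      r2 <- min(cor(g_std[, ve], g_std[, vh])^2, 1)
      if (r2 <= r2_min) next
      out[[length(out) + 1L]] <- data.frame(
        gene_id = gid, peak_id = pid, lead_eqtl = ve, lead_hqtl = vh,
        r2 = r2, distance = d,
        n_closer_genes = closer_gene_count(pa, ga, genes),
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out) %||% data.frame()
  if (nrow(res) && !is.null(mhc)) {
    va <- reference_genotypes$annot
    pos_e <- va$pos[match(res$lead_eqtl, va$variant_id)]
    pos_h <- va$pos[match(res$lead_hqtl, va$variant_id)]
    chr <- va$chrom[match(res$lead_eqtl, va$variant_id)]
    drop <- in_interval(chr, pos_e, mhc) | in_interval(chr, pos_h, mhc)
    pk <- peaks[match(res$peak_id, peaks$feature_id), ]
    drop <- drop | in_interval(pk$chrom, pk$start, mhc)
    res <- res[!drop, , drop = FALSE]
  }
  res
}

#' Link GWAS loci to trait-relevant regulatory elements
#'
#' A peak with a significant hQTL is linked to a GWAS locus when its
#' lead hQTL is in high LD (`r^2 > r2_min`, strict) with the locus lead
#' variant. Signals in the MHC region are excluded.
#'
#' @param gwas_loci Locus data frame from [define_loci()].
#' @param hqtl_leads Data frame `feature_id`, `lead_variant`.
#' @param peaks Peak annotation.
#' @inheritParams coregulated_pairs
#' @return Data frame: `locus_id`, `peak_id`, `lead_gwas`, `lead_hqtl`,
#'   `r2`.
#' @export
gwas_hqtl_links <- function(gwas_loci, hqtl_leads, peaks,
                            reference_genotypes, r2_min = 0.8,
                            mhc = mhc_interval()) {
  g_std <- standardize_cols(reference_genotypes$dosages)
  va <- reference_genotypes$annot
  out <- list()
  for (i in seq_len(nrow(gwas_loci))) {
    vl <- gwas_loci$lead_variant[i]
    if (!vl %in% colnames(g_std) || is.na(g_std[1, vl])) next
    for (j in seq_len(nrow(hqtl_leads))) {
      vh <- hqtl_leads$lead_variant[j]
      if (!vh %in% colnames(g_std) || is.na(g_std[1, vh])) next
      r2 <- min(cor(g_std[, vl], g_std[, vh])^2, 1)
      if (r2 <= r2_min) next
      out[[length(out) + 1L]] <- data.frame(
        locus_id = gwas_loci$locus_id[i],
        peak_id = hqtl_leads$feature_id[j],
        lead_gwas = vl, lead_hqtl = vh, r2 = r2,
        stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out) %||% data.frame()
  if (nrow(res) && !is.null(mhc)) {
    pos_g <- va$pos[match(res$lead_gwas, va$variant_id)]
    pos_h <- va$pos[match(res$lead_hqtl, va$variant_id)]
    chr <- va$chrom[match(res$lead_gwas, va$variant_id)]
    pk <- peaks[match(res$peak_id, peaks$feature_id), ]
    drop <- in_interval(chr, pos_g, mhc) | in_interval(chr, pos_h, mhc) |
      in_interval(pk$chrom, pk$start, mhc)
    res <- res[!drop, , drop = FALSE]
  }
  res
}

#' Merge interaction calls across fragment resolutions
#'
#' Union of the 1-fragment and 4-fragment call sets, removing any
#' 4-fragment call whose other-end interval contains (same bait gene,
#' same chromosome) the other-end interval of a 1-fragment call.
#' Idempotent and order-invariant.
#'
#' @param calls_1frag,calls_4frag Interaction-call data frames (see
#'   [interaction_calls()]); resolutions are taken from the arguments,
#'   not the `resolution` column.
#' @return Merged interaction-call data frame.
#' @export
merge_resolutions <- function(calls_1frag, calls_4frag) {
  if (!nrow(calls_4frag %||% data.frame()))
    return(calls_1frag)
  if (!nrow(calls_1frag %||% data.frame()))
    return(calls_4frag)
  keep <- vapply(seq_len(nrow(calls_4frag)), function(i) {
    c4 <- calls_4frag[i, ]
    hit <- calls_1frag$bait_gene == c4$bait_gene &
      calls_1frag$oe_chrom == c4$oe_chrom &
      calls_1frag$oe_start >= c4$oe_start &
      calls_1frag$oe_end <= c4$oe_end
    !any(hit)
  }, logical(1))
  out <- rbind(calls_1frag, calls_4frag[keep, , drop = FALSE])
  rownames(out) <- NULL
  out
}

#' Assign peaks to interacting genes
#'
#' A peak maps to every bait gene whose interaction call's other-end
#' interval overlaps the peak interval by at least 1 bp (half-open:
#' touching intervals do not overlap).
#'
#' @param peaks Peak annotation (`feature_id`, `chrom`, `start`, `end`).
#' @param merged_calls Merged interaction-call data frame.
#' @param min_score Minimum interaction score for a call to count.
#' @return Named list mapping each peak id to a character vector of
#'   gene ids (possibly empty).
#' @export
assign_peak_genes <- function(peaks, merged_calls, min_score = 5) {
  calls <- merged_calls[merged_calls$score >= min_score, , drop = FALSE]
  empty <- setNames(rep(list(character(0)), nrow(peaks)),
                    peaks$feature_id)
  if (!nrow(calls) || !nrow(peaks)) return(empty)
  # 0-based half-open -> 1-based closed for GRanges
  pg <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(peaks$start + 1L,
                                                peaks$end))
  cg <- GenomicRanges::GRanges(calls$oe_chrom,
                               IRanges::IRanges(calls$oe_start + 1L,
                                                calls$oe_end))
  ov <- GenomicRanges::findOverlaps(pg, cg)
  res <- empty
  if (length(ov)) {
    sp <- split(calls$bait_gene[S4Vectors::subjectHits(ov)],
                peaks$feature_id[S4Vectors::queryHits(ov)])
    for (nm in names(sp)) res[[nm]] <- sort(unique(sp[[nm]]))
  }
  res
}

#' Number of genes closer to a peak than a target gene
#'
#' Counts the other genes whose TSS-to-peak distance (0 when the TSS
#' lies inside the peak, otherwise the gap to the nearest edge) is
#' strictly smaller than the target gene's.
#'
#' @param peak One-row peak annotation (`chrom`, `start`, `end`).
#' @param target_gene One-row gene annotation (`feature_id`, `chrom`,
#'   `tss`).
#' @param all_genes Gene annotation data frame.
#' @return Integer count.
#' @export
closer_gene_count <- function(peak, target_gene, all_genes) {
  others <- all_genes[all_genes$feature_id != target_gene$feature_id &
                        all_genes$chrom == peak$chrom, , drop = FALSE]
  d_target <- peak_tss_distance(peak$start, peak$end, target_gene$tss)
  if (!nrow(others)) return(0L)
  d <- peak_tss_distance(peak$start, peak$end, others$tss)
  sum(d < d_target)
}

#' Interacting-gene eQTL p-values: hQTL peaks versus background
#'
#' Pools the cis-eQTL p-values of every (variant inside peak,
#' interacting gene) pair for a set of hQTL peaks and for a background
#' set of non-hQTL peaks, and compares the two distributions with a
#' one-sided Wilcoxon rank-sum test (alternative: hQTL-set p-values are
#' smaller).
#'
#' @param hqtl_peaks,background_peaks Peak annotation data frames.
#' @param peak_gene_map Named list peak id -> interacting gene ids, as
#'   from [assign_peak_genes()].
#' @param eqtl_associations Nominal association data frame
#'   (`feature_id`, `variant_id`, `p`) from [nominal_scan()].
#' @param variants Variant annotation (`variant_id`, `chrom`, `pos`).
#' @return List: `p_value`, `n_hqtl`, `n_background`, and the two
#'   pooled p-value vectors.
#' @export
interacting_vs_background_eqtl_p <- function(hqtl_peaks, background_peaks,
                                             peak_gene_map,
                                             eqtl_associations, variants) {
  pool <- function(pk) {
    ps <- numeric(0)
    for (i in seq_len(nrow(pk))) {
      p <- pk[i, ]
      genes <- peak_gene_map[[p$feature_id]]
      if (!length(genes)) next
      vin <- variants$variant_id[variants$chrom == p$chrom &
                                   variants$pos >= p$start &
                                   variants$pos < p$end]
      if (!length(vin)) next
      hit <- eqtl_associations$feature_id %in% genes &
        eqtl_associations$variant_id %in% vin
      ps <- c(ps, eqtl_associations$p[hit])
    }
    ps
  }
  hq <- pool(hqtl_peaks)
  bg <- pool(background_peaks)
  if (!length(hq) || !length(bg))
    stopf("no pooled eQTL p-values for one of the peak sets")
  w <- wilcox.test(hq, bg, alternative = "less", exact = FALSE)
  list(p_value = w$p.value, n_hqtl = length(hq), n_background = length(bg),
       hqtl_p = hq, background_p = bg)
}
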