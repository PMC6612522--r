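# Promoter-capture interaction calls at two fragment resolutions and
# per-variant annotations for matched-SNP sampling.

#' Validate a table of promoter-capture interaction calls
#'
#' @param calls Data frame with columns `bait_gene`, `bait_chrom`,
#'   `bait_start`, `bait_end`, `oe_chrom`, `oe_start`, `oe_end`,
#'   `score`, `resolution` (`"1frag"` or `"4frag"`); intervals 0-based
#'   half-open.
#' @param min_score Call threshold; retained calls must score at least
#'   this (the conventional interaction-score cutoff of 5).
#' @return The validated data frame (invisibly the same object).
#' @export
interaction_calls <- function(calls, min_score = 5) {
  need <- c("bait_gene", "bait_chrom", "bait_start", "bait_end",
            "oe_chrom", "oe_start", "oe_end", "score", "resolution")
  miss <- setdiff(need, names(calls))
  if (length(miss))
    stopf("interaction calls missing column(s): %s",
          paste(miss, collapse = ", "))
  if (nrow(calls)) {
    if (any(calls$bait_end <= calls$bait_start) ||
        any(calls$oe_end <= calls$oe_start))
      stopf("interaction intervals must satisfy end > start")
    if (any(calls$score < min_score))
      stopf("interaction scores below the call threshold of %g", min_score)
    if (!all(calls$resolution %in% c("1frag", "4frag")))
      stopf("resolution must be '1frag' or '4frag'")
  }
  calls
}

#' Simulate promoter-capture interaction calls
#'
#' Emits bait-promoter to peak contacts at the high (1-fragment) and low
#' (4-fragment) resolutions. Each peak interacts with its neighbouring
#' gene; a configurable fraction of 4-fragment calls contain a
#' 1-fragment call with the same bait (the case the resolution-merge
#' rule removes), the rest are resolution-exclusive. All emitted calls
#' score at least 5, and peak-promoter pairs are within 1 Mb by
#' construction.
#'
#' @param genes Gene annotation (as from [sim_gene_annot()]).
#' @param peaks Peak annotation with a `near_gene` column (as from
#'   [sim_peak_annot()]).
#' @param config A [sim_config()].
#' @param containment_fraction Fraction of 4-fragment calls whose
#'   other-end contains a same-bait 1-fragment call.
#' @param frag1_pad,frag4_pad Half-open padding (bp) around the peak for
#'   the 1- and 4-fragment other-end intervals.
#' @param seed Integer seed.
#' @return Data frame of interaction calls (see [interaction_calls()]).
#' @export
simulate_interactions <- function(genes, peaks, config,
                                  containment_fraction = 0.5,
                                  frag1_pad = 100L, frag4_pad = 1500L,
                                  seed = NULL) {
  seed <- seed %||% (config$seed + 811L)
  with_seed(seed, {
    gi <- match(peaks$near_gene, genes$feature_id)
    bait <- data.frame(bait_gene = genes$feature_id[gi],
                       bait_chrom = genes$chrom[gi],
                       bait_start = pmax(0L, genes$tss[gi] - 500L),
                       bait_end = genes$tss[gi] + 500L)
    oe1 <- data.frame(oe_chrom = peaks$chrom,
                      oe_start = pmax(0L, peaks$start - frag1_pad),
                      oe_end = peaks$end + frag1_pad)
    oe4 <- data.frame(oe_chrom = peaks$chrom,
                      oe_start = pmax(0L, peaks$start - frag4_pad),
                      oe_end = peaks$end + frag4_pad)
    contained <- runif(nrow(peaks)) < containment_fraction
    score <- function(k) round(runif(k, 5, 25), 2)
    both1 <- cbind(bait[contained, , drop = FALSE],
                   oe1[contained, , drop = FALSE])
    both4 <- cbind(bait[contained, , drop = FALSE],
                   oe4[contained, , drop = FALSE])
    only4 <- cbind(bait[!contained, , drop = FALSE],
                   oe4[!contained, , drop = FALSE])
    calls <- rbind(
      if (nrow(both1)) cbind(both1, score = score(nrow(both1)),
                             resolution = "1frag"),
      if (nrow(both4)) cbind(both4, score = score(nrow(both4)),
                             resolution = "4frag"),
      if (nrow(only4)) cbind(only4, score = score(nrow(only4)),
                             resolution = "4frag"))
    rownames(calls) <- NULL
    interaction_calls(calls)
  })
}

#' Per-variant annotation table for matched-SNP sampling
#'
#' For every variant of a panel: minor allele frequency, gene density
#' (TSSs within `radius`), distance to the nearest gene TSS, and the
#' LD-buddy count (other variants with `r^2 >=` `buddy_r2`).
#'
#' @param genotypes A [genotype_matrix()].
#' @param genes Gene annotation with `chrom` and `tss`.
#' @param radius Radius (bp) for the gene-density count.
#' @param buddy_r2 LD threshold defining a buddy.
#' @return Data frame: `variant_id`, `maf`, `gene_density`,
#'   `dist_nearest_gene`, `ld_buddies`.
#' @export
simulate_snp_annotations <- function(genotypes, genes, radius = 100000L,
                                     buddy_r2 = 0.5) {
  va <- genotypes$annot
  g_std <- standardize_cols(genotypes$dosages)
  g_std[, is.na(g_std[1, ])] <- 0
  R2 <- (crossprod(g_std) / (nrow(g_std) - 1))^2
  same_chr <- outer(va$chrom, va$chrom, "==")
  buddies <- rowSums(R2 >= buddy_r2 & same_chr) - 1L
  density <- integer(nrow(va))
  nearest <- numeric(nrow(va))
  for (ch in unique(va$chrom)) {
    vi <- which(va$chrom == ch)
    tss <- genes$tss[genes$chrom == ch]
    if (!length(tss)) {
      density[vi] <- 0L
      nearest[vi] <- Inf
      next
    }
    d <- abs(outer(va$pos[vi], tss, "-"))
    density[vi] <- rowSums(d <= radius)
    nearest[vi] <- apply(d, 1, min)
  }
  data.frame(variant_id = va$variant_id, maf = va$maf,
             gene_density = density, dist_nearest_gene = nearest,
             ld_buddies = buddies, row.names = NULL,
             stringsAsFactors = FALSE)
}
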