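# Multi-cohort genotype simulation with block-structured LD.
#
# LD is generated by a Gaussian copula: within each block of consecutive
# variants, each haplotype draws an equicorrelated latent vector (shared
# block factor plus idiosyncratic noise) which is thresholded at the
# variant's target allele frequency. Two haplotypes per sample are summed
# to dosages in {0, 1, 2}.

# Variant annotation shared by all cohorts: ids, positions on one
# synthetic chromosome, per-variant target MAF, and LD block membership.
sim_variant_frame <- function(config) {
  m <- config$n_variants
  blk <- as.integer(ceiling(seq_len(m) / config$ld_block_size))
  maf_t <- with_seed(config$seed + 11L, {
    # one target MAF per LD block: variants in strong LD share allele
    # frequencies, and equal thresholds keep the realized dosage r^2
    # close to the latent block correlation
    runif(max(blk), config$maf_range[1], config$maf_range[2])[blk]
  })
  data.frame(
    variant_id = sprintf("var%05d", seq_len(m)),
    chrom = config$chrom,
    pos = as.integer(seq_len(m)) * config$variant_spacing,
    maf_target = maf_t,
    block = blk,
    stringsAsFactors = FALSE)
}

# Draw one haplotype's latent Gaussian matrix (n x m) for the block copula.
draw_latent <- function(n, block, rho) {
  n_blocks <- max(block)
  shared <- matrix(rnorm(n * n_blocks), n, n_blocks)
  eps <- matrix(rnorm(n * length(block)), n, length(block))
  sqrt(rho) * shared[, block, drop = FALSE] + sqrt(1 - rho) * eps
}

# Dosage matrix for n samples at variants with the given target MAFs and
# block structure. Returns {0,1,2} dosages of the minor allele.
draw_block_dosages <- function(n, maf_target, block, rho) {
  thr <- qnorm(maf_target)
  h1 <- sweep(draw_latent(n, block, rho), 2, thr, "<")
  h2 <- sweep(draw_latent(n, block, rho), 2, thr, "<")
  matrix(as.numeric(h1) + as.numeric(h2), n, length(maf_target))
}

#' Simulate a cohort genotype matrix
#'
#' Dosages in `{0, 1, 2}` are drawn from block-correlated latent
#' haplotypes (Gaussian copula, equicorrelated within blocks). Variants
#' whose realized cohort MAF falls below 5% are redrawn (idiosyncratic
#' component only, preserving the block factor) and dropped if they still
#' fail, mirroring the standard MAF < 5% exclusion applied to imputed
#' genotype panels.
#'
#' @param config A [sim_config()].
#' @param cohort_index Which cohort to generate (1-based).
#' @param maf_min Realized-MAF floor for retaining a variant.
#' @return A [genotype_matrix()] with variant coordinates strictly
#'   increasing; carries a `sim` attribute used by [simulate_gwas()] to
#'   regenerate matched large-cohort genotypes.
#' @export
simulate_genotypes <- function(config, cohort_index, maf_min = 0.05) {
  stopifnot(inherits(config, "sim_config"))
  if (cohort_index < 1 || cohort_index > length(config$n_samples_per_cohort))
    stopf("cohort_index %d out of range", cohort_index)
  vf <- sim_variant_frame(config)
  n <- config$n_samples_per_cohort[cohort_index]
  rho <- config$within_block_corr
  seed_c <- (config$seed * 131L + 7919L * as.integer(cohort_index)) %%
    2147483646L + 1L
  dos <- with_seed(seed_c, {
    thr <- qnorm(vf$maf_target)
    l1 <- draw_latent(n, vf$block, rho)
    l2 <- draw_latent(n, vf$block, rho)
    d <- (sweep(l1, 2, thr, "<") + 0) + (sweep(l2, 2, thr, "<") + 0)
    # redraw idiosyncratic noise for variants failing the MAF floor
    for (attempt in seq_len(20)) {
      f <- colMeans(d) / 2
      fail <- which(pmin(f, 1 - f) < maf_min)
      if (!length(fail)) break
      for (j in fail) {
        # a fresh marginal draw; the column loses its block coupling but
        # keeps its target frequency (rare at the default MAF range)
        a1 <- rnorm(n)
        a2 <- rnorm(n)
        d[, j] <- (a1 < thr[j]) + (a2 < thr[j])
      }
    }
    d
  })
  f <- colMeans(dos) / 2
  keep <- pmin(f, 1 - f) >= maf_min
  vf <- vf[keep, , drop = FALSE]
  dos <- dos[, keep, drop = FALSE]
  rownames(dos) <- sprintf("c%d_s%03d", cohort_index, seq_len(n))
  colnames(dos) <- vf$variant_id
  annot <- data.frame(variant_id = vf$variant_id, chrom = vf$chrom,
                      pos = vf$pos, maf = pmin(f, 1 - f)[keep],
                      stringsAsFactors = FALSE)
  g <- genotype_matrix(dos, annot)
  attr(g, "sim") <- list(maf_target = vf$maf_target, block = vf$block,
                         rho = rho)
  g
}
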