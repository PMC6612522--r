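# Configuration for the synthetic multi-cohort study generator.

#' Simulation configuration
#'
#' Describes a synthetic multi-cohort molecular QTL study: three liver
#' cohorts of unequal size by default (49/96/96, echoing a deceased-donor
#' cohort plus two larger panels), block-structured linkage
#' disequilibrium, and planted cis effects on gene expression and histone
#' peak activity. The generator functions are pure functions of this
#' configuration: the same config yields byte-identical output.
#'
#' @param n_samples_per_cohort Integer vector of cohort sizes.
#' @param n_variants Number of variants on the simulated chromosome.
#' @param n_genes Number of genes.
#' @param n_peaks Number of histone peaks.
#' @param ld_block_size Variants per LD block (equicorrelated latent).
#' @param within_block_corr Latent correlation within a block, in `[0, 1)`.
#' @param maf_range Length-2 numeric, target minor allele frequency range
#'   in `(0, 0.5]`.
#' @param effect_size_sd Standard deviation of planted standardized
#'   effect sizes (0 disables all effects).
#' @param effect_size Optional fixed magnitude for planted effects; when
#'   set, every planted beta is `±effect_size` with random sign and
#'   `effect_size_sd` is ignored.
#' @param fraction_features_with_qtl Fraction of features carrying a
#'   planted cis QTL, in `[0, 1]`.
#' @param noise_model `"gaussian"` (expression) or `"negative_binomial"`
#'   (peak counts) residual model for the count-valued generator.
#' @param variant_spacing Base pairs between adjacent variants.
#' @param chrom Chromosome label used for all simulated coordinates.
#' @param seed Integer master seed.
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(n_samples_per_cohort = c(49L, 96L, 96L),
                       n_variants = 500L,
                       n_genes = 20L,
                       n_peaks = 20L,
                       ld_block_size = 10L,
                       within_block_corr = 0.8,
                       maf_range = c(0.1, 0.5),
                       effect_size_sd = 0.5,
                       effect_size = NULL,
                       fraction_features_with_qtl = 0.5,
                       noise_model = c("gaussian", "negative_binomial"),
                       variant_spacing = 2000L,
                       chrom = "chr1",
                       seed = 1L) {
  noise_model <- match.arg(noise_model)
  counts <- c(n_samples_per_cohort, n_variants, n_genes, n_peaks,
              ld_block_size, variant_spacing)
  if (any(counts <= 0) || any(counts != floor(counts)))
    stopf("all counts in sim_config must be positive integers")
  if (length(maf_range) != 2 || maf_range[1] > maf_range[2] ||
      maf_range[1] <= 0 || maf_range[2] > 0.5)
    stopf("maf_range must be increasing and within (0, 0.5]")
  if (within_block_corr < 0 || within_block_corr >= 1)
    stopf("within_block_corr must lie in [0, 1)")
  if (effect_size_sd < 0) stopf("effect_size_sd must be >= 0")
  if (fraction_features_with_qtl < 0 || fraction_features_with_qtl > 1)
    stopf("fraction_features_with_qtl must lie in [0, 1]")
  structure(list(
    n_samples_per_cohort = as.integer(n_samples_per_cohort),
    n_variants = as.integer(n_variants),
    n_genes = as.integer(n_genes),
    n_peaks = as.integer(n_peaks),
    ld_block_size = as.integer(ld_block_size),
    within_block_corr = within_block_corr,
    maf_range = maf_range,
    effect_size_sd = effect_size_sd,
    effect_size = effect_size,
    fraction_features_with_qtl = fraction_features_with_qtl,
    noise_model = noise_model,
    variant_spacing = as.integer(variant_spacing),
    chrom = chrom,
    seed = as.integer(seed)), class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat(sprintf(paste0(
    "sim_config: cohorts n = %s; %d variants (blocks of %d, rho = %.2f); ",
    "%d genes, %d peaks; seed %d\n"),
    paste(x$n_samples_per_cohort, collapse = "/"), x$n_variants,
    x$ld_block_size, x$within_block_corr, x$n_genes, x$n_peaks, x$seed))
  invisible(x)
}
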