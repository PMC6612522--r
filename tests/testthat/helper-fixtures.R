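# Small in-code fixtures shared across test files.

tiny_config <- function(seed = 1L, ...) {
  sim_config(n_samples_per_cohort = c(49L, 96L, 96L), n_variants = 200L,
             n_genes = 8L, n_peaks = 8L, ld_block_size = 10L,
             within_block_corr = 0.8, seed = seed, ...)
}

# A cohort bundle (genotypes + normalized expression + covariates) for
# scan-level tests.
tiny_cohort <- function(cohort_index = 1L, config = tiny_config(),
                        covariates = TRUE) {
  g <- simulate_genotypes(config, cohort_index)
  genes <- sim_gene_annot(config)
  truth <- plant_truth(g, genes, config, "gene")
  cov <- if (covariates) {
    cv <- simulate_covariates(nrow(g$dosages),
                              seed = config$seed + cohort_index)
    rownames(cv) <- rownames(g$dosages)
    cv
  } else NULL
  expr <- simulate_expression(g, truth, config, covariates = cov)
  list(genotypes = g, truth = truth,
       phenotype = normalize_phenotypes(expr, log_transform = FALSE),
       covariates = cov, genes = genes)
}

# Independent-variant genotype panel (no LD) with given size.
flat_genotypes <- function(n = 60L, m = 40L, seed = 3L, maf = NULL) {
  cfg <- sim_config(n_samples_per_cohort = n, n_variants = m,
                    ld_block_size = 1L, within_block_corr = 0,
                    seed = seed)
  simulate_genotypes(cfg, 1L)
}

# Minimal interaction-call row builder.
call_row <- function(bait, oe_start, oe_end, resolution,
                     score = 10, chrom = "chr1", bait_start = 0L,
                     bait_end = 1000L) {
  data.frame(bait_gene = bait, bait_chrom = chrom,
             bait_start = bait_start, bait_end = bait_end,
             oe_chrom = chrom, oe_start = oe_start, oe_end = oe_end,
             score = score, resolution = resolution,
             stringsAsFactors = FALSE)
}
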