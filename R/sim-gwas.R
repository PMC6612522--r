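# GWAS summary-statistic simulation over the reference LD structure.

#' Simulate GWAS summary statistics for a locus
#'
#' Generates per-variant marginal association statistics (beta, SE, z,
#' p, N, MAF) for a large GWAS cohort at the variants of a reference
#' genotype panel. The causal variant either coincides with a molecular
#' trait's planted variant (`shared = TRUE`) or is drawn from variants
#' in low LD with it, so that colocalization of shared versus distinct
#' architectures can be tested against known truth.
#'
#' Two generation modes: `"cohort"` simulates an explicit cohort of
#' `n_gwas` individuals with the same LD-block copula as the reference
#' panel and computes marginal regressions (assumption-free, slower);
#' `"analytic"` draws the marginal z-vector from its multivariate normal
#' approximation `z ~ MVN(sqrt(n) R lambda, R)` using the reference LD
#' matrix `R` (fast, used for large replicate studies).
#'
#' @param genotypes Reference [genotype_matrix()] (carries the copula
#'   parameters when produced by [simulate_genotypes()]).
#' @param causal_variant Variant id of the molecular trait's causal
#'   variant (anchor for shared/distinct placement); may be `NA` with
#'   `h2_locus = 0`.
#' @param n_gwas GWAS sample size.
#' @param h2_locus Fraction of trait variance explained by the causal
#'   variant, in `[0, 1)`; 0 yields a null locus.
#' @param shared If `TRUE` the GWAS causal variant is `causal_variant`;
#'   otherwise a variant with reference `r^2 < distinct_max_r2` to it.
#' @param distinct_max_r2 LD ceiling for choosing a distinct causal
#'   variant.
#' @param method `"cohort"` or `"analytic"` (see above).
#' @param seed Integer seed.
#' @return Data frame of class `gwas_summary` with one row per variant:
#'   `variant_id`, `chrom`, `pos`, `beta`, `se`, `z`, `p`, `n`, `maf`,
#'   plus attribute `"truth"` (list `causal_variant`, `shared`,
#'   `h2_locus`).
#' @export
simulate_gwas <- function(genotypes, causal_variant, n_gwas = 50000L,
                          h2_locus = 0.001, shared = TRUE,
                          distinct_max_r2 = 0.5,
                          method = c("cohort", "analytic"), seed = 1L) {
  method <- match.arg(method)
  if (h2_locus < 0 || h2_locus >= 1) stopf("h2_locus must lie in [0, 1)")
  va <- genotypes$annot
  m <- nrow(va)
  g_std <- standardize_cols(genotypes$dosages)
  poly <- !is.na(g_std[1, ])
  gwas_causal <- NA_character_
  if (h2_locus > 0) {
    if (is.na(causal_variant) || !causal_variant %in% va$variant_id)
      stopf("causal_variant not found in the reference panel")
    if (shared) {
      gwas_causal <- causal_variant
    } else {
      r2 <- drop(crossprod(g_std[, causal_variant],
                           g_std[, poly, drop = FALSE]) /
                   (nrow(g_std) - 1))^2
      pool <- colnames(g_std[, poly, drop = FALSE])[r2 < distinct_max_r2]
      pool <- setdiff(pool, causal_variant)
      if (!length(pool))
        stopf("no variant with r^2 < %.2f to '%s' available",
              distinct_max_r2, causal_variant)
      gwas_causal <- with_seed(seed + 13L, sample(pool, 1L))
    }
  }
  b <- sqrt(h2_locus)
  res <- with_seed(seed, {
    if (method == "cohort") {
      sim <- attr(genotypes, "sim")
      if (is.null(sim))
        stopf(
          "cohort-mode GWAS simulation needs a simulate_genotypes() panel")
      G <- draw_block_dosages(n_gwas, sim$maf_target, sim$block, sim$rho)
      colnames(G) <- va$variant_id
      y <- rnorm(n_gwas, sd = sqrt(1 - h2_locus))
      if (h2_locus > 0) {
        gc <- G[, gwas_causal]
        y <- y + b * (gc - mean(gc)) / max(sd(gc), 1e-12)
      }
      gs <- standardize_cols(G)
      r <- drop(crossprod(gs, (y - mean(y)) / sd(y))) / (n_gwas - 1)
      r[is.na(r)] <- 0
      df <- n_gwas - 2L
      p <- cor_pvalue(r, df)
      sy <- sd(y)
      sx <- apply(G, 2, sd)
      sx[sx == 0] <- NA
      beta <- r * sy / sx
      se <- (sy / sx) * sqrt(pmax(1 - r^2, 0) / df)
      maf <- pmin(colMeans(G) / 2, 1 - colMeans(G) / 2)
      list(beta = beta, se = se, z = r * sqrt(df / pmax(1 - r^2, 1e-300)),
           p = p, maf = maf)
    } else {
      R <- crossprod(g_std[, poly, drop = FALSE]) / (nrow(g_std) - 1)
      # ridge for numerical positive definiteness of the sample LD matrix
      R <- 0.995 * R + 0.005 * diag(nrow(R))
      lambda <- rep(0, nrow(R))
      if (h2_locus > 0)
        lambda[match(gwas_causal, rownames(R))] <- b
      mu <- sqrt(n_gwas) * drop(R %*% lambda)
      z <- mu + drop(rnorm(nrow(R)) %*% chol(R))
      zfull <- rep(NA_real_, m)
      zfull[poly] <- z
      se <- 1 / sqrt(2 * va$maf * (1 - va$maf) * n_gwas)
      list(beta = zfull * se, se = se, z = zfull,
           p = pmax(2 * pnorm(abs(zfull), lower.tail = FALSE),
                    .Machine$double.xmin),
           maf = va$maf)
    }
  })
  out <- data.frame(variant_id = va$variant_id, chrom = va$chrom,
                    pos = va$pos, beta = res$beta, se = res$se, z = res$z,
                    p = res$p, n = n_gwas, maf = res$maf,
                    row.names = NULL, stringsAsFactors = FALSE)
  out <- out[!is.na(out$z), , drop = FALSE]
  attr(out, "truth") <- list(causal_variant = gwas_causal, shared = shared,
                             h2_locus = h2_locus)
  class(out) <- c("gwas_summary", "data.frame")
  out
}
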