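# All permutations of 1..n (used to build a worst-case observed
# statistic for the rank-logic check).
all_perms <- function(n) {
  if (n == 1) return(matrix(1L))
  sub <- all_perms(n - 1)
  do.call(rbind, lapply(seq_len(n), function(k) {
    rest <- seq_len(n)[-k]
    cbind(k, matrix(rest[sub], nrow(sub)))
  }))
}

test_that("an observed minimum above every permuted minimum gives p near 1", {
  g <- flat_genotypes(n = 7L, m = 3L, seed = 41L)
  win <- list(chrom = "chr1", start = 0L, end = max(g$annot$pos) + 1L,
              closed = FALSE)
  base <- c(-1.2, -0.7, -0.1, 0.1, 0.4, 0.9, 1.6)
  # pick the arrangement of `base` whose strongest cis correlation is the
  # weakest over all 7! arrangements: every permutation then does better
  P <- all_perms(7)
  gs <- scale(g$dosages)
  best <- apply(abs(crossprod(gs, apply(P, 1, function(ix) base[ix]))) / 6,
                2, max)
  y <- setNames(base[P[which.min(best), ]], rownames(g$dosages))
  suppressWarnings(
    rec <- permutation_adjusted_p(g, y, NULL, win, n_perm = 500,
                                  seed = 2L))
  expect_gt(rec$adjusted_p, 0.99)
  expect_gt(rec$empirical_p, 0.99)
})

test_that("adjusted p-values are uniform under the null", {
  g <- flat_genotypes(n = 50L, m = 20L, seed = 42L)
  win <- list(chrom = "chr1", start = 0L, end = max(g$annot$pos) + 1L,
              closed = FALSE)
  set.seed(7)
  adj <- vapply(1:400, function(r) {
    y <- setNames(rnorm(50), rownames(g$dosages))
    permutation_adjusted_p(g, y, NULL, win, n_perm = 150,
                           seed = 1000L + r)$adjusted_p
  }, numeric(1))
  expect_gt(suppressWarnings(ks.test(adj, "punif"))$p.value, 0.01)
})

test_that("beta-approximated p tracks the direct empirical permutation p", {
  cfg <- sim_config(n_samples_per_cohort = 96L, n_variants = 60L,
                    n_genes = 60L, effect_size_sd = 0.3,
                    fraction_features_with_qtl = 0.5, seed = 43L)
  g <- simulate_genotypes(cfg, 1)
  tr <- plant_truth(g, sim_gene_annot(cfg), cfg, "gene")
  nn <- normalize_phenotypes(simulate_expression(g, tr, cfg),
                             log_transform = FALSE)
  leads <- scan_leads(g, nn, kind = "gene", n_perm = 1000, seed = 3L)
  expect_gt(cor(leads$adjusted_p, leads$empirical_p, method = "spearman"),
            0.95)
})

test_that("lead ties break by position then id and p is monotone in (a, b)", {
  # duplicated dosage column: identical p; the smaller position wins
  dos <- cbind(v2 = c(0, 1, 2, 1, 0, 2, 1, 0),
               v1 = c(0, 1, 2, 1, 0, 2, 1, 0),
               v3 = c(2, 0, 1, 0, 2, 1, 0, 1))
  rownames(dos) <- sprintf("s%d", 1:8)
  ann <- data.frame(variant_id = c("v2", "v1", "v3"), chrom = "chr1",
                    pos = c(200L, 100L, 300L), maf = rep(0.4, 3))
  g <- genotype_matrix(dos, ann)
  y <- setNames(c(0.1, 1.1, 2.2, 0.9, -0.2, 2.1, 1.2, 0.05),
                rownames(dos))
  win <- list(chrom = "chr1", start = 0L, end = 400L, closed = FALSE)
  rec <- permutation_adjusted_p(g, y, NULL, win, n_perm = 200, seed = 4L)
  expect_identical(rec$lead_variant, "v1")
  # for fixed fitted (a, b), the adjustment is monotone in nominal p
  expect_true(all(diff(pbeta(sort(runif(50)), rec$beta_a,
                             rec$beta_b)) >= 0))
})

test_that("power rises monotonically with the planted effect size", {
  g <- flat_genotypes(n = 96L, m = 15L, seed = 44L)
  win <- list(chrom = "chr1", start = 0L, end = max(g$annot$pos) + 1L,
              closed = FALSE)
  gs <- scale(g$dosages[, 8])
  betas <- c(0, 0.2, 0.4, 0.6, 0.8)
  set.seed(9)
  power <- vapply(betas, function(b) {
    hits <- vapply(1:30, function(r) {
      y <- setNames(drop(b * gs + rnorm(96)), rownames(g$dosages))
      permutation_adjusted_p(g, y, NULL, win, n_perm = 150,
                             seed = r)$adjusted_p < 0.05
    }, logical(1))
    mean(hits)
  }, numeric(1))
  expect_gt(cor(betas, power, method = "spearman"), 0.9)
})

test_that("tiny permutation counts warn and covariates are respected", {
  g <- flat_genotypes(n = 40L, m = 5L, seed = 45L)
  win <- list(chrom = "chr1", start = 0L, end = max(g$annot$pos) + 1L,
              closed = FALSE)
  cov <- matrix(rnorm(40), 40, dimnames = list(rownames(g$dosages), "c1"))
  y <- setNames(rnorm(40) + cov[, 1], rownames(g$dosages))
  expect_warning(permutation_adjusted_p(g, y, cov, win, n_perm = 50,
                                        seed = 1L), "small")
  r1 <- permutation_adjusted_p(g, y, cov, win, n_perm = 300, seed = 1L)
  r2 <- permutation_adjusted_p(g, y, cov, win, n_perm = 300, seed = 1L,
                               permute = "raw")
  expect_true(is.finite(r1$adjusted_p) && is.finite(r2$adjusted_p))
})
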