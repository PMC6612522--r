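test_that("tissue-sharing classification applies the count cutoffs", {
  expect_identical(classify_sharing(rep(1, 43)), "shared")
  expect_identical(classify_sharing(rep(0, 43)), "liver_specific")
  # exactly 5 tissues above 0.9: not liver-specific ("fewer than 5")
  m <- c(rep(0.95, 5), rep(0.1, 38))
  expect_identical(classify_sharing(m), "neither")
  expect_identical(classify_sharing(c(rep(0.95, 4), rep(0.1, 39))),
                   "liver_specific")
  expect_identical(classify_sharing(c(rep(0.95, 38), rep(0.1, 5))),
                   "shared")
  expect_error(classify_sharing(c(1.2, rep(0, 42))), "0, 1")
})

fake_annotation <- function(n = 200L, seed = 71L) {
  set.seed(seed)
  data.frame(variant_id = sprintf("s%04d", 1:n),
             maf = runif(n, 0.05, 0.5),
             gene_density = sample(1:8, n, replace = TRUE),
             dist_nearest_gene = sample.int(200000L, n),
             ld_buddies = sample(0:12, n, replace = TRUE),
             stringsAsFactors = FALSE)
}

test_that("matched sampler satisfies every criterion bound", {
  ann <- fake_annotation()
  targets <- ann$variant_id[1:5]
  crit <- match_criteria(maf_tolerance = 0.1, gene_density_tolerance = 0.5,
                         distance_tolerance = 1, buddies_tolerance = 1,
                         n_sets = 100L)
  sets <- sample_matched_snps(targets, ann, crit, seed = 4L)
  expect_length(sets, 100L)
  for (s in sets) {
    expect_length(s, 5L)
    expect_false(anyDuplicated(s) > 0)
    for (i in seq_along(targets)) {
      t <- ann[ann$variant_id == targets[i], ]
      m <- ann[ann$variant_id == s[i], ]
      expect_false(s[i] == targets[i])
      expect_lte(abs(m$maf - t$maf), crit$maf_tolerance + 1e-12)
      expect_lte(m$gene_density, t$gene_density * 1.5 + 1e-9)
      expect_gte(m$gene_density, t$gene_density * 0.5 - 1e-9)
      expect_lte(m$dist_nearest_gene, t$dist_nearest_gene * 2 + 1e-9)
      expect_lte(m$ld_buddies, t$ld_buddies * 2 + 1e-9)
    }
  }
  expect_identical(sample_matched_snps(targets, ann, crit, seed = 4L),
                   sets)
})

test_that("exact annotation duplicates always admit a matched set", {
  ann <- fake_annotation(20L)
  dup <- transform(ann[1:3, ], variant_id = paste0(variant_id, "_dup"))
  pool <- rbind(ann, dup)
  sets <- sample_matched_snps(ann$variant_id[1:3], pool,
                              match_criteria(n_sets = 10L), seed = 1L)
  expect_length(sets, 10L)
})

test_that("impossible targets widen with a warning, then error", {
  ann <- fake_annotation(30L)
  lonely <- data.frame(variant_id = "lonely", maf = 0.49,
                       gene_density = 100L, dist_nearest_gene = 1L,
                       ld_buddies = 50L)
  ann2 <- rbind(ann, lonely)
  warns <- capture_warnings(
    expect_error(sample_matched_snps("lonely", ann2,
                                     match_criteria(n_sets = 2L),
                                     seed = 1L),
                 "no eligible"))
  expect_equal(length(warns), 3L)  # three stepwise widening rounds
  expect_true(all(grepl("widening", warns)))
})

test_that("overlap enrichment matches hypergeometric enumeration", {
  # one-sided hypergeometric tail oracle for a 2x2 table
  hyper_p <- function(a, b, c, d) {
    sum(dhyper(a:min(a + b, a + c), a + b, c + d, a + c))
  }
  # build target/feature/null fixtures realizing the table (8,2;4,6)
  features <- data.frame(chrom = "chr1", start = 0L, end = 10L)
  mk_set <- function(k_in, k_out)
    data.frame(chrom = "chr1", pos = c(rep(5L, k_in),
                                       seq(100L, by = 10L,
                                           length.out = k_out)))
  got <- overlap_enrichment(mk_set(8, 2), features, list(mk_set(4, 6)))
  expect_equal(got$observed, 8L)
  expect_equal(got$fisher_p, hyper_p(8, 2, 4, 6), tolerance = 1e-12)
  expect_equal(got$odds_ratio, (8 * 6) / (2 * 4), tolerance = 1e-12)
  # complete separation: tiny p, Haldane-corrected OR flagged
  sep <- overlap_enrichment(mk_set(20, 0), features,
                            list(mk_set(0, 20)))
  expect_lt(sep$fisher_p, 1e-9)
  expect_true(sep$or_corrected)
  # a target set drawn from the null itself is unremarkable
  same <- overlap_enrichment(mk_set(3, 7), features,
                             list(mk_set(3, 7), mk_set(3, 7)))
  expect_gte(same$fisher_p, 0.5)
  expect_equal(same$odds_ratio, 1, tolerance = 1e-12)
})

test_that("permutation proportion p uses the add-one rule", {
  expect_equal(permutation_proportion_test(50, 10, rep(0, 999)), 0.001)
  expect_equal(permutation_proportion_test(0, 10, rep(5, 99)), 1)
  p_mid <- permutation_proportion_test(5, 10, c(rep(0, 50), rep(9, 49)))
  expect_gt(p_mid, 0.4)
  expect_lt(p_mid, 0.6)
  expect_gt(permutation_proportion_test(1e9, 10, rep(0, 999)), 0)
})

test_that("random region sets preserve lengths and respect bounds", {
  targets <- data.frame(chrom = "chr1", start = c(0L, 100L),
                        end = c(500L, 4100L))
  genome <- data.frame(chrom = c("chrA", "chrB"),
                       length = c(100000L, 5000L))
  sets <- random_region_sets(targets, genome, n_sets = 200L, seed = 9L)
  for (s in sets) {
    expect_setequal(s$end - s$start, c(500L, 4000L))
    L <- genome$length[match(s$chrom, genome$chrom)]
    expect_true(all(s$start >= 0 & s$end <= L))
  }
  expect_identical(random_region_sets(targets, genome, n_sets = 200L,
                                      seed = 9L), sets)
  # excluded intervals are avoided
  excl <- data.frame(chrom = "chrA", start = 0L, end = 99000L)
  sets2 <- random_region_sets(targets[1, ], genome, n_sets = 50L,
                              seed = 2L, exclude = excl)
  for (s in sets2)
    expect_false(any(s$chrom == "chrA" & s$start < 99000L))
})
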