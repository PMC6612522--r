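test_that("ld_r2 is symmetric, flip-invariant, and matches the oracle", {
  g <- flat_genotypes(n = 80L, m = 10L, seed = 61L)
  v <- g$annot$variant_id
  expect_equal(ld_r2(g, v[1], v[1]), 1)
  # allele flip: dosage 2 - x has identical r^2
  dos <- g$dosages
  dos <- cbind(dos, flip = 2 - dos[, 1])
  ann <- rbind(g$annot, data.frame(variant_id = "flip", chrom = "chr1",
                                   pos = max(g$annot$pos) + 100L,
                                   maf = g$annot$maf[1]))
  g2 <- genotype_matrix(dos, ann)
  expect_equal(ld_r2(g2, v[1], "flip"), 1, tolerance = 1e-12)
  expect_equal(ld_r2(g, v[2], v[5]), ld_r2(g, v[5], v[2]))
  expect_equal(ld_r2(g, v[2], v[5]), cor(g$dosages[, 2], g$dosages[, 5])^2,
               tolerance = 1e-12)
  mono <- genotype_matrix(cbind(g$dosages[, 1:2], m0 = rep(1, 80)),
                          rbind(g$annot[1:2, ],
                                data.frame(variant_id = "m0",
                                           chrom = "chr1",
                                           pos = max(g$annot$pos) + 200L,
                                           maf = 0.5)))
  expect_error(ld_r2(mono, v[1], "m0"), "monomorphic")
  expect_error(ld_r2(g, v[1], "nope"), "not in the reference")
})

brute_merge <- function(c1, c4) {
  keep <- rep(TRUE, nrow(c4))
  for (i in seq_len(nrow(c4)))
    for (j in seq_len(nrow(c1)))
      if (c1$bait_gene[j] == c4$bait_gene[i] &&
          c1$oe_chrom[j] == c4$oe_chrom[i] &&
          c1$oe_start[j] >= c4$oe_start[i] &&
          c1$oe_end[j] <= c4$oe_end[i]) keep[i] <- FALSE
  rbind(c1, c4[keep, , drop = FALSE])
}

test_that("resolution merge removes containing 4-fragment calls", {
  c1 <- call_row("gA", 400L, 700L, "1frag")
  c4 <- rbind(call_row("gA", 100L, 1800L, "4frag"),   # contains -> drop
              call_row("gB", 100L, 1800L, "4frag"),   # other bait -> keep
              call_row("gA", 500L, 600L, "4frag"))    # does not contain
  m <- merge_resolutions(c1, c4)
  expect_equal(nrow(m), 3L)
  expect_false(any(m$bait_gene == "gA" & m$oe_start == 100L))
  expect_identical(merge_resolutions(c1, c4[0, ]), c1)
  expect_identical(merge_resolutions(c1[0, ], c4), c4)
})

test_that("merge is idempotent, order-invariant, and matches brute force", {
  set.seed(62)
  for (r in 1:40) {
    mk <- function(k, res) {
      s <- sample.int(2000L, k)
      do.call(rbind, lapply(seq_len(k), function(i)
        call_row(sample(c("gA", "gB", "gC"), 1), s[i],
                 s[i] + sample.int(900L, 1), res)))
    }
    c1 <- mk(sample(1:6, 1), "1frag")
    c4 <- mk(sample(1:8, 1), "4frag")
    m <- merge_resolutions(c1, c4)
    b <- brute_merge(c1, c4)
    expect_equal(m[order(m$oe_start, m$bait_gene), ],
                 b[order(b$oe_start, b$bait_gene), ],
                 ignore_attr = TRUE)
    m1 <- m[m$resolution == "1frag", , drop = FALSE]
    m4 <- m[m$resolution == "4frag", , drop = FALSE]
    again <- merge_resolutions(m1, m4)
    expect_equal(nrow(again), nrow(m))
    shuf <- merge_resolutions(c1[sample(nrow(c1)), , drop = FALSE],
                              c4[sample(nrow(c4)), , drop = FALSE])
    expect_equal(nrow(shuf), nrow(m))
  }
})

test_that("peak-to-gene assignment uses half-open overlap", {
  peaks <- data.frame(feature_id = c("p1", "p2", "p3"), chrom = "chr1",
                      start = c(1000L, 5000L, 9000L),
                      end = c(2000L, 6000L, 9500L))
  calls <- rbind(call_row("gA", 1500L, 1600L, "1frag"),
                 call_row("gB", 2000L, 2500L, "1frag"),  # touches p1 only
                 call_row("gC", 5500L, 5600L, "1frag", score = 4))
  map <- assign_peak_genes(peaks, calls)
  expect_identical(map$p1, "gA")
  expect_identical(map$p2, character(0))  # gC call below score threshold
  expect_identical(map$p3, character(0))
  # brute-force interval join on random fixtures
  set.seed(63)
  for (r in 1:10) {
    pk <- data.frame(feature_id = sprintf("p%02d", 1:15), chrom = "chr1",
                     start = sample.int(10000L, 15))
    pk$end <- pk$start + sample.int(500L, 15)
    cl <- do.call(rbind, lapply(1:10, function(i) {
      s <- sample.int(10000L, 1)
      call_row(sample(c("gA", "gB"), 1), s, s + sample.int(800L, 1),
               "1frag")
    }))
    map2 <- assign_peak_genes(pk, cl)
    for (i in seq_len(nrow(pk))) {
      hit <- cl$oe_start < pk$end[i] & pk$start[i] < cl$oe_end
      expect_setequal(map2[[pk$feature_id[i]]],
                      unique(cl$bait_gene[hit]))
    }
  }
})

test_that("closer-gene counting uses the edge-gap distance", {
  peak <- data.frame(chrom = "chr1", start = 10000L, end = 11000L)
  genes <- data.frame(
    feature_id = c("target", "inside", "near", "far", "other_chr"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2"),
    tss = c(20000L, 10500L, 12000L, 90000L, 100L))
  tg <- genes[genes$feature_id == "target", ]
  expect_equal(closer_gene_count(peak, tg, genes), 2L)
  # a TSS inside the peak has distance zero
  expect_equal(closer_gene_count(peak, genes[genes$feature_id ==
                                               "inside", ], genes), 0L)
  # removing a gene that is not nearer leaves the count unchanged
  expect_equal(closer_gene_count(peak, tg,
                                 genes[genes$feature_id != "far", ]), 2L)
})

test_that("co-regulation pairing applies LD and MHC rules", {
  g <- flat_genotypes(n = 150L, m = 20L, seed = 64L)
  v <- g$annot$variant_id
  genes <- data.frame(feature_id = "gA", chrom = "chr1", tss = 5000L)
  peaks <- data.frame(feature_id = "pA", chrom = "chr1",
                      start = 15000L, end = 16000L)
  eq <- data.frame(feature_id = "gA", lead_variant = v[3])
  # identical leads: r^2 = 1 -> paired
  hq <- data.frame(feature_id = "pA", lead_variant = v[3])
  got <- coregulated_pairs(eq, hq, genes, peaks, g, mhc = NULL)
  expect_equal(nrow(got), 1L)
  expect_equal(got$r2, 1)
  # independent leads: not paired
  hq2 <- data.frame(feature_id = "pA", lead_variant = v[15])
  expect_equal(nrow(coregulated_pairs(eq, hq2, genes, peaks, g,
                                      mhc = NULL)), 0L)
  # pairs inside the MHC interval are excluded
  g_mhc <- genotype_matrix(g$dosages,
                           transform(g$annot, chrom = "chr6",
                                     pos = pos + 28510120L))
  genes6 <- data.frame(feature_id = "gA", chrom = "chr6",
                       tss = 28515120L)
  peaks6 <- data.frame(feature_id = "pA", chrom = "chr6",
                       start = 28525120L, end = 28526120L)
  expect_equal(nrow(coregulated_pairs(eq, hq, genes6, peaks6, g_mhc)),
               0L)
  expect_gt(nrow(coregulated_pairs(eq, hq, genes6, peaks6, g_mhc,
                                   mhc = NULL)), 0L)
})

test_that("GWAS-peak links require strict r2 > 0.8", {
  g <- flat_genotypes(n = 150L, m = 12L, seed = 65L)
  v <- g$annot$variant_id
  loci <- data.frame(locus_id = "L1", lead_variant = v[2],
                     chrom = "chr1", start = 0L, end = 2000000L)
  peaks <- data.frame(feature_id = "pA", chrom = "chr1",
                      start = 100L, end = 600L)
  hq_same <- data.frame(feature_id = "pA", lead_variant = v[2])
  got <- gwas_hqtl_links(loci, hq_same, peaks, g, mhc = NULL)
  expect_equal(nrow(got), 1L)
  hq_indep <- data.frame(feature_id = "pA", lead_variant = v[9])
  expect_equal(nrow(gwas_hqtl_links(loci, hq_indep, peaks, g,
                                    mhc = NULL)), 0L)
})

test_that("interaction-informed eQTL comparison matches the rank-sum test", {
  v <- data.frame(variant_id = sprintf("v%d", 1:6), chrom = "chr1",
                  pos = c(150L, 250L, 1150L, 1250L, 5000L, 6000L))
  peaks <- data.frame(feature_id = c("hq", "bg"), chrom = "chr1",
                      start = c(100L, 1100L), end = c(300L, 1300L))
  map <- list(hq = "gA", bg = "gB")
  assoc <- data.frame(
    feature_id = c("gA", "gA", "gB", "gB"),
    variant_id = c("v1", "v2", "v3", "v4"),
    p = c(0.001, 0.02, 0.4, 0.6))
  got <- interacting_vs_background_eqtl_p(peaks[1, ], peaks[2, ], map,
                                          assoc, v)
  oracle <- wilcox.test(c(0.001, 0.02), c(0.4, 0.6),
                        alternative = "less", exact = FALSE)$p.value
  expect_equal(got$p_value, oracle)
  # identical distributions give p near 0.5
  assoc2 <- transform(assoc, p = rep(c(0.3, 0.5), 2))
  same <- interacting_vs_background_eqtl_p(peaks[1, ], peaks[2, ], map,
                                           assoc2, v)
  expect_gt(same$p_value, 0.3)
})
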