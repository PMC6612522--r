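make_fm <- function(values, ids = colnames(values)) {
  n <- ncol(values)
  feature_matrix(values,
                 data.frame(feature_id = ids, chrom = "chr1",
                            start = seq_len(n) * 1000L,
                            end = seq_len(n) * 1000L + 500L,
                            tss = seq_len(n) * 1000L,
                            stringsAsFactors = FALSE))
}

test_that("expressed-gene filter matches a brute-force evaluation", {
  set.seed(1)
  n <- 10L; m <- 30L
  cnt <- matrix(rpois(n * m, 8), n,
                dimnames = list(sprintf("s%02d", 1:n),
                                sprintf("g%02d", 1:m)))
  tpm <- matrix(rexp(n * m, 4), n, dimnames = dimnames(cnt))
  cnt[, 1] <- 0  # all-zero feature must be excluded
  keep <- filter_expressed(make_fm(cnt), make_fm(tpm))
  brute <- colnames(cnt)[vapply(seq_len(m), function(j)
    sum(cnt[, j] > 6 & tpm[, j] > 0.1) >= ceiling(0.1 * n), logical(1))]
  expect_identical(keep, brute)
  expect_false("g01" %in% keep)
  # n = 10: passing in exactly one sample suffices (10% of subjects)
  cnt2 <- matrix(0, n, 1, dimnames = list(rownames(cnt), "solo"))
  tpm2 <- cnt2
  cnt2[4, 1] <- 10; tpm2[4, 1] <- 1
  expect_identical(filter_expressed(make_fm(cnt2), make_fm(tpm2)), "solo")
  expect_error(filter_expressed(make_fm(cnt),
                                make_fm(tpm[n:1, ])), "sample")
})

test_that("peak filter keeps means of at least 20, boundary included", {
  v <- cbind(zero = rep(0, 5), edge = rep(20, 5), low = rep(19.9, 5),
             hi = rep(25, 5))
  rownames(v) <- sprintf("s%d", 1:5)
  keep <- filter_peaks(make_fm(v))
  expect_identical(sort(keep), c("edge", "hi"))
})

test_that("normalization yields Blom scores invariant to monotone maps", {
  set.seed(2)
  v <- matrix(rexp(50 * 6), 50, dimnames = list(sprintf("s%02d", 1:50),
                                                sprintf("g%d", 1:6)))
  nn <- normalize_phenotypes(make_fm(v))
  expect_true(all(abs(colMeans(nn$values)) < 0.05))
  expect_true(all(abs(apply(nn$values, 2, sd) - 1) < 0.1))
  # each feature is a permutation of one fixed score vector
  ref <- unname(sort(nn$values[, 1]))
  for (j in 2:6) expect_equal(unname(sort(nn$values[, j])), ref)
  # monotone transform of the input leaves the output unchanged
  nn2 <- normalize_phenotypes(make_fm(v^3))
  expect_equal(nn$values, nn2$values, tolerance = 1e-12)
})

test_that("zero-variance features are flagged out of normalization", {
  v <- cbind(a = c(1, 5, 2, 8), b = rep(3, 4))
  rownames(v) <- sprintf("s%d", 1:4)
  nn <- normalize_phenotypes(make_fm(v), log_transform = FALSE)
  expect_identical(attr(nn, "flagged"), "b")
  expect_identical(colnames(nn$values), "a")
})

test_that("cis windows follow the 1 Mb / 10 kb rules with clipping", {
  gene <- data.frame(feature_id = "g", chrom = "chr1", tss = 5000000L)
  w <- cis_window(gene, "gene")
  expect_equal(c(w$start, w$end), c(4000000L, 6000000L))
  peak <- data.frame(feature_id = "p", chrom = "chr1",
                     start = 50000L, end = 51000L)
  wp <- cis_window(peak, "peak")
  expect_equal(c(wp$start, wp$end), c(40000L, 61000L))
  expect_false(wp$closed)
  near <- data.frame(feature_id = "g2", chrom = "chr1", tss = 500000L)
  expect_equal(cis_window(near, "gene")$start, 0L)
})

test_that("residualization matches the projection oracle and is idempotent", {
  set.seed(3)
  n <- 40L
  X <- cbind(rnorm(n), rbinom(n, 1, 0.5))
  y <- matrix(rnorm(n * 3), n)
  r <- residualize(y, X)
  # hat-matrix oracle
  D <- cbind(1, X)
  H <- D %*% solve(crossprod(D)) %*% t(D)
  expect_equal(r, (diag(n) - H) %*% y, tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_lt(max(abs(crossprod(cbind(1, X), r))), 1e-8)
  expect_equal(residualize(r, X), r, tolerance = 1e-10)
  # intercept only mean-centers; exact linear dependence gives ~0
  expect_equal(residualize(y), sweep(y, 2, colMeans(y)),
               tolerance = 1e-12)
  expect_lt(max(abs(residualize(2 + 3 * X[, 1], X))), 1e-10)
  expect_error(residualize(y, cbind(a = X[, 1], b = 2 * X[, 1])),
               "collinear")
})

test_that("nominal scan matches the closed-form correlation t-test", {
  # construct a phenotype with a known correlation to one variant
  g <- flat_genotypes(n = 20L, m = 5L, seed = 4L)
  set.seed(5)
  target_r <- 0.5
  gs <- scale(g$dosages[, 3])
  repeat {
    e <- scale(residualize(rnorm(20), gs))
    y <- target_r * gs + sqrt(1 - target_r^2) * e
    if (abs(cor(y, gs) - target_r) < 1e-10) break
  }
  fm <- feature_matrix(matrix(y, 20, dimnames = list(rownames(g$dosages),
                                                     "f1")),
                       data.frame(feature_id = "f1", chrom = "chr1",
                                  start = 1L, end = 2L, tss = 1L))
  win <- list(chrom = "chr1", start = 0L,
              end = max(g$annot$pos) + 1L, closed = FALSE)
  sc <- nominal_scan(g, fm, windows = list(f1 = win))
  row <- sc[sc$variant_id == g$annot$variant_id[3], ]
  t_expected <- target_r * sqrt((20 - 2) / (1 - target_r^2))
  expect_equal(row$r, target_r, tolerance = 1e-8)
  expect_equal(row$p, 2 * pt(t_expected, 18, lower.tail = FALSE),
               tolerance = 1e-8)
})

test_that("scan handles perfect association, empty windows, bad input", {
  g <- flat_genotypes(n = 30L, m = 4L, seed = 6L)
  y <- g$dosages[, 2]
  fm <- feature_matrix(matrix(y, 30, dimnames = list(rownames(g$dosages),
                                                     "f1")),
                       data.frame(feature_id = "f1", chrom = "chr1",
                                  start = 1L, end = 2L, tss = 1L))
  win_all <- list(chrom = "chr1", start = 0L,
                  end = max(g$annot$pos) + 1L, closed = FALSE)
  sc <- nominal_scan(g, fm, windows = list(f1 = win_all))
  expect_equal(sc$p[sc$variant_id == g$annot$variant_id[2]],
               .Machine$double.xmin)
  # empty window -> zero records, no error
  win_empty <- list(chrom = "chr9", start = 0L, end = 10L, closed = FALSE)
  expect_equal(nrow(nominal_scan(g, fm, windows = list(f1 = win_empty))),
               0L)
  fm_const <- feature_matrix(matrix(1, 30,
                                    dimnames = list(rownames(g$dosages),
                                                    "f1")),
                             fm$annot)
  expect_error(nominal_scan(g, fm_const, windows = list(f1 = win_all)),
               "constant")
})

test_that("trans set excludes pairs at exactly 5 Mb", {
  feat <- data.frame(feature_id = "g", chrom = "chr1", tss = 10000000L)
  vars <- data.frame(
    variant_id = c("a", "b", "c", "d"),
    chrom = c("chr2", "chr1", "chr1", "chr1"),
    pos = c(1L, 15000000L, 15000001L, 9990000L))
  tp <- trans_pairs(feat, vars, "gene")
  expect_true("a" %in% tp)          # other chromosome
  expect_false("b" %in% tp)         # exactly 5 Mb: still cis
  expect_true("c" %in% tp)          # 5 Mb + 1
  expect_false("d" %in% tp)
})
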