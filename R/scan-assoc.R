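# Nominal cis association scan (Pearson correlation t-tests) and the
# beta-approximated permutation p-value for the per-feature lead variant.

#' Residualize columns on a covariate matrix
#'
#' Least-squares residuals of each column of `values` on `covariates`
#' plus an intercept. With no covariates this mean-centers the input.
#'
#' @param values Numeric matrix (samples x columns) or vector.
#' @param covariates Optional numeric matrix (samples x k).
#' @return Residual matrix with the dimensions of `values`.
#' @export
residualize <- function(values, covariates = NULL) {
  v <- as.matrix(values)
  X <- cbind(`(intercept)` = rep(1, nrow(v)),
             if (!is.null(covariates)) as.matrix(covariates))
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    drop <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stopf("covariate matrix is rank deficient; collinear column(s): %s",
          paste(drop, collapse = ", "))
  }
  r <- qr.resid(qx, v)
  dimnames(r) <- dimnames(v)
  r
}

# Correlation of residualized, standardized genotype columns with a
# residualized, standardized phenotype matrix. Returns variants x
# phenotype-columns matrix of r.
resid_cor <- function(g_std, y_std) {
  crossprod(g_std, y_std) / (nrow(g_std) - 1)
}

#' Nominal cis association scan
#'
#' For every feature, tests each variant inside its cis window by the
#' Pearson product-moment correlation between covariate-residualized
#' dosage and phenotype, with the two-sided t test on `n - 2 - k`
#' degrees of freedom (`k` covariates).
#'
#' @param genotypes A [genotype_matrix()].
#' @param phenotype A [feature_matrix()] (normalized phenotypes).
#' @param covariates Optional sample x k covariate matrix.
#' @param kind `"gene"` (1 Mb TSS window) or `"peak"` (10 kb interval
#'   window); ignored for features listed in `windows`.
#' @param windows Optional named list of precomputed windows (as from
#'   [cis_window()]) keyed by feature id.
#' @return Data frame with one row per (feature, variant-in-window)
#'   pair: `feature_id`, `variant_id`, `slope`, `se`, `r`, `t`, `p`,
#'   `n`. Monomorphic variants are skipped and reported in the
#'   `"skipped"` attribute.
#' @export
nominal_scan <- function(genotypes, phenotype, covariates = NULL,
                         kind = c("gene", "peak"), windows = NULL) {
  kind <- match.arg(kind)
  if (!identical(rownames(genotypes$dosages), rownames(phenotype$values)))
    stopf("genotype and phenotype sample ids differ")
  n <- nrow(genotypes$dosages)
  k <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  df <- n - 2L - k
  if (df < 1) stopf("not enough samples for %d covariates", k)
  const <- apply(phenotype$values, 2, sd) == 0
  if (any(const))
    stopf("constant phenotype feature(s): %s",
          paste(utils::head(colnames(phenotype$values)[const], 5),
                collapse = ", "))
  g_res <- residualize(genotypes$dosages, covariates)
  y_res <- residualize(phenotype$values, covariates)
  g_std <- standardize_cols(g_res)
  y_std <- standardize_cols(y_res)
  g_sd <- apply(g_res, 2, sd)
  y_sd <- apply(y_res, 2, sd)
  mono <- colnames(genotypes$dosages)[is.na(g_std[1, ])]
  out <- vector("list", ncol(phenotype$values))
  skipped <- character(0)
  for (i in seq_len(ncol(phenotype$values))) {
    feat <- phenotype$annot[i, ]
    w <- windows[[feat$feature_id]] %||% cis_window(feat, kind)
    vids <- window_variants(genotypes, w)
    sk <- intersect(vids, mono)
    if (length(sk)) skipped <- c(skipped, sk)
    vids <- setdiff(vids, mono)
    if (!length(vids)) next
    r <- drop(resid_cor(g_std[, vids, drop = FALSE],
                        y_std[, i, drop = FALSE]))
    p <- cor_pvalue(r, df)
    t <- sign(r) * abs(r) * sqrt(df / pmax(1 - r^2, .Machine$double.xmin))
    slope <- r * y_sd[i] / g_sd[vids]
    se <- (y_sd[i] / g_sd[vids]) * sqrt(pmax(1 - r^2, 0) / df)
    out[[i]] <- data.frame(feature_id = feat$feature_id, variant_id = vids,
                           slope = slope, se = se, r = r, t = t, p = p,
                           n = n, row.names = NULL,
                           stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out) %||% data.frame()
  if (length(skipped))
    attr(res, "skipped") <- data.frame(variant_id = unique(skipped),
                                       reason = "monomorphic")
  res
}

# Beta(a, b) fit by maximum likelihood with method-of-moments
# initialization. Returns list(a, b, ok).
fit_beta_mle <- function(x) {
  eps <- 1e-12
  x <- pmin(pmax(x, eps), 1 - eps)
  m <- mean(x); v <- var(x)
  if (!is.finite(v) || v <= 0) return(list(a = NA_real_, b = NA_real_,
                                           ok = FALSE))
  s <- m * (1 - m) / v - 1
  init <- log(pmax(c(m * s, (1 - m) * s), 1e-3))
  nll <- function(par) {
    a <- exp(par[1]); b <- exp(par[2])
    -sum(stats::dbeta(x, a, b, log = TRUE))
  }
  fit <- tryCatch(optim(init, nll, method = "BFGS"), error = function(e) NULL)
  if (is.null(fit) || !is.finite(fit$value))
    return(list(a = NA_real_, b = NA_real_, ok = FALSE))
  list(a = exp(fit$par[1]), b = exp(fit$par[2]), ok = TRUE)
}

#' Permutation-adjusted p-value for a feature's lead variant
#'
#' Permutes the (covariate-residualized) phenotype across samples,
#' records the minimum nominal p-value over the cis window for each
#' permutation, fits a Beta(a, b) distribution to the permuted minima by
#' maximum likelihood, and reports `adjusted_p = BetaCDF(observed min
#' p)`. The lead variant is the nominal argmin, ties broken by smallest
#' genomic position then lexicographic id. If the beta fit fails the
#' empirical permutation p `(count + 1) / (n_perm + 1)` is used instead.
#'
#' @param genotypes A [genotype_matrix()].
#' @param y Named numeric phenotype vector (names = sample ids).
#' @param covariates Optional covariate matrix.
#' @param window Window as from [cis_window()].
#' @param n_perm Number of permutations.
#' @param seed Integer seed for the permutation stream.
#' @param permute Permute the residualized phenotype against fixed
#'   residualized genotypes (`"residualized"`, the default scheme of
#'   permutation-based cis scans) or the raw phenotype with
#'   re-residualization per permutation (`"raw"`).
#' @return One-row data frame: `lead_variant`, `nominal_p`,
#'   `adjusted_p`, `empirical_p`, `beta_a`, `beta_b`, `n_perm`,
#'   `n_variants`.
#' @export
permutation_adjusted_p <- function(genotypes, y, covariates = NULL,
                                   window, n_perm = 10000L, seed = 1L,
                                   permute = c("residualized", "raw")) {
  permute <- match.arg(permute)
  if (n_perm < 100)
    warnf("n_perm = %d is very small; the beta approximation is unreliable",
          n_perm)
  vids <- window_variants(genotypes, window)
  if (!length(vids)) stopf("no variants in window")
  y <- y[rownames(genotypes$dosages)]
  if (anyNA(y)) stopf("phenotype missing for some genotyped samples")
  if (sd(y) == 0) stopf("constant phenotype")
  n <- length(y)
  k <- if (is.null(covariates)) 0L else ncol(as.matrix(covariates))
  df <- n - 2L - k
  g_std <- standardize_cols(residualize(genotypes$dosages[, vids,
                                                          drop = FALSE],
                                        covariates))
  mono <- is.na(g_std[1, ])
  g_std <- g_std[, !mono, drop = FALSE]
  vids <- vids[!mono]
  if (!length(vids)) stopf("all variants in window are monomorphic")
  y_res <- drop(residualize(y, covariates))
  y_std <- (y_res - mean(y_res)) / sd(y_res)
  r_obs <- drop(crossprod(g_std, y_std)) / (n - 1)
  p_obs <- cor_pvalue(r_obs, df)
  pos <- genotypes$annot$pos[match(vids, genotypes$annot$variant_id)]
  lead_i <- order(p_obs, pos, vids)[1]
  obs_min <- min(p_obs)
  perm_min <- with_seed(seed, {
    if (permute == "residualized") {
      yp <- vapply(seq_len(n_perm), function(i) y_std[sample.int(n)],
                   numeric(n))
    } else {
      yp <- vapply(seq_len(n_perm), function(i) y[sample.int(n)],
                   numeric(n))
      yp <- standardize_cols(residualize(yp, covariates))
    }
    rmax <- apply(abs(crossprod(g_std, yp)) / (n - 1), 2, max)
    cor_pvalue(rmax, df)
  })
  emp <- (1 + sum(perm_min <= obs_min)) / (n_perm + 1)
  fit <- fit_beta_mle(perm_min)
  adj <- if (fit$ok) pbeta(obs_min, fit$a, fit$b) else emp
  adj <- max(adj, .Machine$double.xmin)
  data.frame(lead_variant = vids[lead_i], nominal_p = obs_min,
             adjusted_p = adj, empirical_p = emp,
             beta_a = fit$a, beta_b = fit$b, n_perm = n_perm,
             n_variants = length(vids), stringsAsFactors = FALSE)
}

#' Per-feature lead scan with permutation-adjusted p-values
#'
#' Applies [permutation_adjusted_p()] to every feature of a phenotype
#' matrix over its cis window.
#'
#' @inheritParams nominal_scan
#' @param n_perm,seed,permute Passed to [permutation_adjusted_p()]; each
#'   feature gets an independent permutation stream derived from `seed`.
#' @return Data frame with one row per feature (columns of
#'   [permutation_adjusted_p()] plus `feature_id`), features without cis
#'   variants omitted.
#' @export
scan_leads <- function(genotypes, phenotype, covariates = NULL,
                       kind = c("gene", "peak"), n_perm = 1000L, seed = 1L,
                       permute = c("residualized", "raw")) {
  kind <- match.arg(kind)
  permute <- match.arg(permute)
  out <- vector("list", ncol(phenotype$values))
  for (i in seq_len(ncol(phenotype$values))) {
    feat <- phenotype$annot[i, ]
    w <- cis_window(feat, kind)
    if (!length(window_variants(genotypes, w))) next
    rec <- permutation_adjusted_p(
      genotypes, setNames(phenotype$values[, i],
                          rownames(phenotype$values)),
      covariates, w, n_perm = n_perm,
      seed = (seed + 7L * i) %% 2147483646L + 1L, permute = permute)
    out[[i]] <- cbind(feature_id = feat$feature_id, rec,
                      stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
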