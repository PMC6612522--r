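# Cross-cohort meta-analysis (sample-size weighted z-scores) and the
# permutation-based empirical FDR used to declare genome-wide
# significance of meta QTL scans.

#' Sample-size weighted z-score meta-analysis
#'
#' Combines per-cohort two-sided p-values with effect directions by the
#' weighted-z (Stouffer) scheme used by standard GWAS meta-analysis
#' software: `z_i = sign_i * qnorm(1 - p_i / 2)`,
#' `z = sum(sqrt(n_i) z_i) / sqrt(sum(n_i))`, meta p `= 2 (1 - Phi(|z|))`.
#'
#' @param p Numeric vector of per-cohort two-sided p-values in `(0, 1]`;
#'   zeros are clamped to the smallest positive double with a warning.
#' @param sign Per-cohort effect direction, `-1` or `+1`.
#' @param n Per-cohort sample sizes.
#' @return List with elements `z` and `p`.
#' @export
stouffer_meta <- function(p, sign, n) {
  if (!length(p)) stopf("at least one cohort is required")
  if (length(sign) != length(p) || length(n) != length(p))
    stopf("p, sign, n must have equal length")
  if (!all(sign %in% c(-1, 1))) stopf("sign must be -1 or +1")
  if (any(p <= 0)) {
    warnf("p = 0 clamped to smallest positive double")
    p <- pmax(p, .Machine$double.xmin)
  }
  if (any(p > 1)) stopf("p-values must be <= 1")
  z_i <- sign * qnorm(p / 2, lower.tail = FALSE)
  z <- sum(sqrt(n) * z_i) / sqrt(sum(n))
  list(z = z, p = min(1, 2 * pnorm(abs(z), lower.tail = FALSE)))
}

# Vectorized weighted-z meta over a variants x cohorts grid with NAs for
# cohorts where a variant is missing.
stouffer_meta_matrix <- function(P, S, n) {
  P <- pmax(P, .Machine$double.xmin)
  Z <- S * qnorm(P / 2, lower.tail = FALSE)
  W <- matrix(sqrt(n), nrow(P), ncol(P), byrow = TRUE)
  W[is.na(Z)] <- NA
  z <- rowSums(Z * W, na.rm = TRUE) / sqrt(rowSums(W^2, na.rm = TRUE))
  list(z = z, p = pmin(1, 2 * pnorm(abs(z), lower.tail = FALSE)))
}

#' Meta-analytic cis scan across cohorts
#'
#' For every feature shared by all cohorts, computes per-variant nominal
#' association statistics within each cohort (correlation t-test on
#' covariate-residualized data), combines them across cohorts with
#' [stouffer_meta()], and records the minimum meta p-value and its lead
#' variant. Variants missing from a cohort (e.g. dropped by its MAF
#' filter) are combined over the cohorts that retain them. With
#' `permute_seed` set, each cohort's sample labels are permuted once
#' before scanning, producing the null minimum-p distribution used by
#' [empirical_fdr()].
#'
#' @param cohorts List of cohorts; each element is a list with
#'   `genotypes` ([genotype_matrix()]), `phenotype` (normalized
#'   [feature_matrix()]), and optional `covariates`.
#' @param kind `"gene"` or `"peak"` (cis-window rule).
#' @param permute_seed Optional integer; permute phenotypes (one draw
#'   per cohort) to generate null statistics.
#' @param keep_records Keep the full per-variant meta records per
#'   feature (needed e.g. for colocalization input).
#' @return List with `leads` (data frame `feature_id`, `lead_variant`,
#'   `min_p`, `n_variants`) and, if requested, `records` (named list of
#'   per-feature data frames with `variant_id`, `z`, `p`, `n_total`).
#' @export
meta_scan <- function(cohorts, kind = c("gene", "peak"),
                      permute_seed = NULL, keep_records = FALSE) {
  kind <- match.arg(kind)
  C <- length(cohorts)
  prep <- vector("list", C)
  for (c in seq_len(C)) {
    co <- cohorts[[c]]
    y <- co$phenotype$values
    if (!is.null(permute_seed)) {
      perm <- with_seed((permute_seed + 37L * c) %% 2147483646L + 1L,
                        sample.int(nrow(y)))
      y <- y[perm, , drop = FALSE]
      rownames(y) <- rownames(co$phenotype$values)
    }
    k <- if (is.null(co$covariates)) 0L else ncol(as.matrix(co$covariates))
    g_std <- standardize_cols(residualize(co$genotypes$dosages,
                                          co$covariates))
    y_std <- standardize_cols(residualize(y, co$covariates))
    prep[[c]] <- list(g_std = g_std, y_std = y_std,
                      n = nrow(y), df = nrow(y) - 2L - k,
                      geno = co$genotypes,
                      mono = colnames(g_std)[is.na(g_std[1, ])])
  }
  feats <- Reduce(intersect,
                  lapply(cohorts, function(co) co$phenotype$annot$feature_id))
  annot <- cohorts[[1]]$phenotype$annot
  all_va <- unique(do.call(rbind, lapply(
    cohorts, function(co) co$genotypes$annot[, c("variant_id", "chrom",
                                                 "pos")])))
  leads <- vector("list", length(feats))
  records <- if (keep_records) vector("list", length(feats)) else NULL
  for (fi in seq_along(feats)) {
    feat <- annot[annot$feature_id == feats[fi], ]
    w <- cis_window(feat, kind)
    per <- lapply(prep, function(pc) {
      vids <- setdiff(window_variants(pc$geno, w), pc$mono)
      if (!length(vids)) return(NULL)
      yi <- pc$y_std[, feat$feature_id]
      r <- drop(crossprod(pc$g_std[, vids, drop = FALSE], yi)) /
        (pc$n - 1)
      list(vids = vids, p = cor_pvalue(r, pc$df),
           s = ifelse(r >= 0, 1, -1))
    })
    union_v <- sort(unique(unlist(lapply(per, function(x) x$vids))))
    if (!length(union_v)) next
    P <- matrix(NA_real_, length(union_v), C,
                dimnames = list(union_v, NULL))
    S <- P
    for (c in seq_len(C)) {
      if (is.null(per[[c]])) next
      P[per[[c]]$vids, c] <- per[[c]]$p
      S[per[[c]]$vids, c] <- per[[c]]$s
    }
    n_c <- vapply(prep, `[[`, numeric(1), "n")
    mm <- stouffer_meta_matrix(P, S, n_c)
    pos <- all_va$pos[match(union_v, all_va$variant_id)]
    lead_i <- order(mm$p, pos, union_v)[1]
    leads[[fi]] <- data.frame(feature_id = feats[fi],
                              lead_variant = union_v[lead_i],
                              min_p = mm$p[lead_i],
                              n_variants = length(union_v),
                              stringsAsFactors = FALSE)
    if (keep_records)
      records[[fi]] <- data.frame(
        variant_id = union_v, z = mm$z, p = mm$p,
        n_total = rowSums(matrix(n_c, length(union_v), C,
                                 byrow = TRUE) * !is.na(P)),
        row.names = NULL, stringsAsFactors = FALSE)
  }
  out <- list(leads = do.call(rbind, leads))
  if (keep_records) {
    names(records) <- feats
    out$records <- records
  }
  out
}

#' Permutation-based empirical FDR threshold
#'
#' Chooses the most permissive p-value threshold `z*` among the observed
#' per-feature minima such that `fraction(null < z) / fraction(true < z)
#' <= q`, where the null minima come from scans of permuted phenotypes.
#' Features with true minimum p strictly below `z*` are declared
#' significant.
#'
#' @param true_min_p Per-feature minimum p-values from the observed scan
#'   (optionally named by feature).
#' @param null_min_p Per-feature minimum p-values from the permuted scan
#'   (may pool several permutation passes).
#' @param q Target FDR in `(0, 1)`.
#' @return List of class `fdr_calibration`: `q`, `threshold` (`NA` when
#'   no candidate satisfies the ratio), `significant` (names or indices),
#'   `n_significant`, `n_features`.
#' @export
empirical_fdr <- function(true_min_p, null_min_p, q = 0.05) {
  if (q <= 0 || q >= 1) stopf("q must lie in (0, 1)")
  if (!length(true_min_p) || !length(null_min_p))
    stopf("both p-value lists must be non-empty")
  cand <- sort(unique(true_min_p))
  frac_true <- vapply(cand, function(z) mean(true_min_p < z), numeric(1))
  frac_null <- vapply(cand, function(z) mean(null_min_p < z), numeric(1))
  ok <- frac_true > 0 & frac_null / frac_true <= q
  threshold <- if (any(ok)) max(cand[ok]) else NA_real_
  sig <- if (is.na(threshold)) logical(length(true_min_p))
  else true_min_p < threshold
  ids <- if (!is.null(names(true_min_p))) names(true_min_p)[sig]
  else which(sig)
  structure(list(q = q, threshold = threshold, significant = ids,
                 n_significant = sum(sig),
                 n_features = length(true_min_p)),
            class = "fdr_calibration")
}

#' @export
print.fdr_calibration <- function(x, ...) {
  cat(sprintf(
    "empirical FDR %.3g: threshold %s; %d / %d features significant\n",
    x$q, format(x$threshold, digits = 4), x$n_significant, x$n_features))
  invisible(x)
}

#' Benjamini-Hochberg significant set
#'
#' Standard step-up FDR correction; returns features whose BH-adjusted
#' p-value is below `q`.
#'
#' @param adjusted_p Named numeric vector of per-feature p-values (e.g.
#'   beta-approximated permutation p-values).
#' @param q Target FDR.
#' @return Character vector of significant feature names (indices when
#'   unnamed).
#' @export
bh_fdr <- function(adjusted_p, q = 0.05) {
  bh <- p.adjust(adjusted_p, method = "BH")
  sig <- bh < q
  if (!is.null(names(adjusted_p))) names(adjusted_p)[sig] else which(sig)
}
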