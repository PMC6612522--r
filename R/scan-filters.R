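# Feature inclusion filters and phenotype normalization.

#' Expressed-gene filter
#'
#' Retains genes with estimated read count above `count_min` and
#' abundance above `tpm_min` in at least `ceiling(sample_fraction * n)`
#' samples, the standard inclusion rule for liver RNA-seq panels.
#'
#' @param counts,tpm [feature_matrix()] objects over the same samples and
#'   features (expected read counts and TPM).
#' @param count_min,tpm_min Strict lower thresholds.
#' @param sample_fraction Fraction of samples that must pass both.
#' @return Character vector of retained feature ids.
#' @export
filter_expressed <- function(counts, tpm, count_min = 6, tpm_min = 0.1,
                             sample_fraction = 0.1) {
  if (!identical(rownames(counts$values), rownames(tpm$values)))
    stopf("count and TPM matrices have mismatched sample sets")
  if (!identical(colnames(counts$values), colnames(tpm$values)))
    stopf("count and TPM matrices have mismatched feature sets")
  need <- ceiling(sample_fraction * nrow(counts$values))
  pass <- colSums(counts$values > count_min & tpm$values > tpm_min) >= need
  colnames(counts$values)[pass]
}

#' Peak inclusion filter
#'
#' Retains histone peaks with a cross-sample mean read count of at least
#' `mean_min`.
#'
#' @param peak_counts A [feature_matrix()] of peak read counts.
#' @param mean_min Inclusive mean-count threshold.
#' @return Character vector of retained peak ids.
#' @export
filter_peaks <- function(peak_counts, mean_min = 20) {
  pass <- colMeans(peak_counts$values) >= mean_min
  colnames(peak_counts$values)[pass]
}

#' Normalize phenotypes for association scanning
#'
#' Three steps: (1) natural-log transform after adding a pseudocount of
#' 1; (2) quantile normalization between individuals across all features
#' (every sample acquires the same empirical distribution); (3)
#' per-feature rank-based inverse-normal transform to standard normal
#' scores (Blom offsets), so each output feature is a permutation of one
#' fixed normal-score vector.
#'
#' Features with zero variance after step 2 cannot be rank-normalized;
#' they are dropped and listed in the `"flagged"` attribute.
#'
#' @param fm A [feature_matrix()] of non-negative values (TPM, FPM, or
#'   counts).
#' @param log_transform Apply step 1 (disable for already-log data).
#' @return A [feature_matrix()] of normal scores, with attribute
#'   `"flagged"` naming excluded zero-variance features.
#' @export
normalize_phenotypes <- function(fm, log_transform = TRUE) {
  v0 <- fm$values
  if (nrow(v0) < 2) stopf("normalization requires >= 2 samples")
  if (log_transform) v0 <- log(v0 + 1)
  # limma normalizes columns to a common distribution; our individuals
  # are rows, so transpose in and out
  v <- t(limma::normalizeQuantiles(t(v0)))
  dimnames(v) <- dimnames(fm$values)
  # a feature constant on input carries no rank information even if the
  # between-individual step lends it spurious variation
  flagged <- colnames(v)[apply(v, 2, function(x) sd(x) == 0 || anyNA(x)) |
                           apply(v0, 2, sd) == 0]
  keep <- setdiff(colnames(v), flagged)
  n <- nrow(v)
  # quantile normalization maps every individual onto one shared value
  # grid, which creates cross-individual ties; break them by the
  # pre-normalization values (then sample order) so ranks are strict
  # and every feature carries the exact Blom score vector
  v <- vapply(keep, function(j) {
    rk <- integer(n)
    rk[order(v[, j], v0[, j])] <- seq_len(n)
    qnorm((rk - 0.375) / (n + 0.25))
  }, numeric(n))
  rownames(v) <- rownames(fm$values)
  out <- feature_matrix(v, fm$annot[fm$annot$feature_id %in% keep, ,
                                    drop = FALSE])
  attr(out, "flagged") <- flagged
  out
}
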