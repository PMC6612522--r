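# GWAS locus definition and approximate-Bayes-factor colocalization of
# a trait with a molecular QTL, with the five-hypothesis posterior
# decomposition (H0 no signal, H1/H2 trait-only, H3 two distinct causal
# variants, H4 one shared causal variant).

#' Define GWAS loci from summary statistics
#'
#' Greedy 2 Mb locus definition: repeatedly take the most significant
#' unmasked variant with `p < p_threshold`, emit the interval 1 Mb up-
#' and downstream of it, and mask all variants within 1 Mb. Ties on p
#' are broken by genomic position.
#'
#' @param summary GWAS summary data frame (`variant_id`, `chrom`, `pos`,
#'   `p`, ...).
#' @param p_threshold Genome-wide locus threshold.
#' @param flank Locus half-width (bp).
#' @return Data frame of loci: `locus_id`, `lead_variant`, `chrom`,
#'   `start`, `end`, `lead_p` (start clipped at 0).
#' @export
define_loci <- function(summary, p_threshold = 1e-6, flank = 1000000L) {
  if (!nrow(summary)) return(data.frame())
  s <- summary[order(summary$p, summary$chrom, summary$pos), ]
  s <- s[s$p < p_threshold, , drop = FALSE]
  loci <- list()
  while (nrow(s)) {
    lead <- s[1, ]
    loci[[length(loci) + 1L]] <- data.frame(
      locus_id = sprintf("locus_%s_%d", lead$chrom, lead$pos),
      lead_variant = lead$variant_id, chrom = lead$chrom,
      start = max(0L, lead$pos - flank), end = lead$pos + flank,
      lead_p = lead$p, stringsAsFactors = FALSE)
    # a candidate closer than the full locus width would overlap the
    # emitted 2 Mb region, so it cannot found a region of its own
    masked <- s$chrom == lead$chrom & abs(s$pos - lead$pos) < 2 * flank
    s <- s[!masked, , drop = FALSE]
  }
  do.call(rbind, loci) %||%
    data.frame(locus_id = character(0), lead_variant = character(0),
               chrom = character(0), start = integer(0),
               end = integer(0), lead_p = numeric(0))
}

#' Wakefield approximate Bayes factor (log scale)
#'
#' `log ABF = 0.5 log(1 - r) + 0.5 r z^2` with shrinkage factor
#' `r = W / (W + se^2)` and `z = beta / se`, where `W` is the prior
#' variance of the effect size.
#'
#' @param beta Estimated effect size(s).
#' @param se Standard error(s), `> 0`.
#' @param prior_sd_W Prior standard deviation of the effect (default
#'   0.15, the conventional choice for quantitative traits; use 0.2 for
#'   binary traits).
#' @return Numeric vector of log ABFs.
#' @export
single_variant_abf <- function(beta, se, prior_sd_W = 0.15) {
  if (any(se <= 0)) stopf("standard errors must be > 0")
  W <- prior_sd_W^2
  r <- W / (W + se^2)
  0.5 * log1p(-r) + 0.5 * r * (beta / se)^2
}

#' Log ABFs from p-values, MAF and sample size
#'
#' Reconstructs `|z| = qnorm(1 - p/2)` and the effective standard error
#' `sqrt(1 / (2 N f (1 - f)))` of a standardized quantitative trait,
#' then applies [single_variant_abf()].
#'
#' @param p Two-sided p-values.
#' @param maf Minor allele frequencies.
#' @param n Sample sizes.
#' @param prior_sd_W Prior effect-size standard deviation.
#' @return Numeric vector of log ABFs.
#' @export
abf_from_pvalues <- function(p, maf, n, prior_sd_W = 0.15) {
  z <- qnorm(pmax(p, .Machine$double.xmin) / 2, lower.tail = FALSE)
  se <- 1 / sqrt(2 * n * maf * (1 - maf))
  single_variant_abf(z * se, se, prior_sd_W)
}

#' Colocalization posteriors from per-variant log ABFs
#'
#' Combines per-variant Wakefield log ABFs of two traits over an
#' identical ordered variant set into posterior probabilities of the
#' five hypotheses, using log-sum-exp accumulation: H1 and H2 sum the
#' single-trait ABFs, H4 sums the same-variant products, and H3 sums all
#' distinct-variant products (`S1 * S2 - S12`).
#'
#' @param abf1,abf2 Numeric vectors of log ABFs, aligned by variant;
#'   names (when present on both) must agree.
#' @param p1,p2 Prior probabilities that a variant is causal for trait 1
#'   / trait 2 only.
#' @param p12 Prior probability that a variant is causal for both.
#' @return List of class `coloc_result`: `pp` (named numeric PP0..PP4),
#'   `n_variants`, `power` (PP3 + PP4), `ratio` (PP4 / (PP3 + PP4), `NA`
#'   when power is 0).
#' @export
coloc_posteriors <- function(abf1, abf2, p1 = 1e-4, p2 = 1e-4,
                             p12 = 1e-5) {
  if (length(abf1) != length(abf2) || !length(abf1))
    stopf("ABF vectors must be non-empty and of equal length")
  if (!is.null(names(abf1)) && !is.null(names(abf2)) &&
      !identical(names(abf1), names(abf2))) {
    bad <- union(setdiff(names(abf1), names(abf2)),
                 setdiff(names(abf2), names(abf1)))
    stopf("variant sets differ or are reordered; offenders: %s",
          paste(utils::head(c(bad, names(abf1)[names(abf1) !=
                                                 names(abf2)]), 5),
                collapse = ", "))
  }
  m <- length(abf1)
  s1 <- logsumexp(abf1)
  s2 <- logsumexp(abf2)
  s12 <- logsumexp(abf1 + abf2)
  lH0 <- 0
  lH1 <- log(p1) + s1
  lH2 <- log(p2) + s2
  lH4 <- log(p12) + s12
  lH3 <- if (m == 1) -Inf else log(p1) + log(p2) + logdiffexp(s1 + s2, s12)
  l <- c(lH0, lH1, lH2, lH3, lH4)
  pp <- exp(l - logsumexp(l))
  pp <- pp / sum(pp)
  names(pp) <- paste0("PP", 0:4)
  power <- pp[["PP3"]] + pp[["PP4"]]
  structure(list(pp = pp, n_variants = m, power = power,
                 ratio = if (power > 0) pp[["PP4"]] / power else NA_real_),
            class = "coloc_result")
}

#' @export
print.coloc_result <- function(x, ...) {
  cat(sprintf("coloc over %d variants: %s; power %.3f, ratio %s -> %s\n",
              x$n_variants,
              paste(sprintf("%s=%.3f", names(x$pp), x$pp), collapse = " "),
              x$power,
              ifelse(is.na(x$ratio), "NA", sprintf("%.3f", x$ratio)),
              classify_coloc(x)))
  invisible(x)
}

#' Classify a colocalization result
#'
#' A pair is testable only with sufficient power (`PP3 + PP4 >
#' power_min`); among testable pairs, `PP4 / (PP3 + PP4) > ratio_min`
#' declares a shared causal variant.
#'
#' @param result A `coloc_result` (or list with `power` and `ratio`).
#' @param power_min Power threshold (exceed to be testable).
#' @param ratio_min Ratio threshold (exceed to colocalize).
#' @return One of `"underpowered"`, `"colocalized"`, `"distinct"`.
#' @export
classify_coloc <- function(result, power_min = 0.8, ratio_min = 0.9) {
  if (result$power <= power_min) return("underpowered")
  if (result$ratio > ratio_min) "colocalized" else "distinct"
}

#' Pair GWAS loci with molecular features
#'
#' Mode `"tss_in_locus"` pairs each locus with significant-eQTL genes
#' whose TSS lies inside the locus (closed interval: a TSS exactly on
#' the boundary is included); mode `"all_within_2Mb"` pairs with every
#' feature in the window regardless of significance (the rescan mode for
#' genes with sub-threshold QTL evidence).
#'
#' @param loci Locus data frame from [define_loci()].
#' @param features Feature annotation (`feature_id`, `chrom`, `tss`),
#'   with a logical `significant` column when using `"tss_in_locus"`.
#' @param mode Pairing mode.
#' @return Data frame with columns `locus_id`, `feature_id`.
#' @export
locus_feature_pairs <- function(loci, features,
                                mode = c("tss_in_locus",
                                         "all_within_2Mb")) {
  mode <- match.arg(mode)
  if (mode == "tss_in_locus") {
    if (!"significant" %in% names(features))
      stopf("mode 'tss_in_locus' needs a logical 'significant' column")
    features <- features[features$significant, , drop = FALSE]
  }
  if (!nrow(loci) || !nrow(features))
    return(data.frame(locus_id = character(0),
                      feature_id = character(0)))
  out <- lapply(seq_len(nrow(loci)), function(i) {
    l <- loci[i, ]
    hit <- features$chrom == l$chrom & features$tss >= l$start &
      features$tss <= l$end
    if (!any(hit)) return(NULL)
    data.frame(locus_id = l$locus_id,
               feature_id = features$feature_id[hit],
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out) %||%
    data.frame(locus_id = character(0), feature_id = character(0))
}

#' Colocalization of a GWAS locus with a molecular QTL
#'
#' Convenience wrapper: harmonizes the two summary tables on shared
#' variant ids (in GWAS position order), computes Wakefield log ABFs for
#' each side, and returns the posterior decomposition. Either side may
#' supply `beta`/`se` columns (preferred) or `p`/`maf`/`n` columns.
#'
#' @param gwas Data frame for the trait side (`variant_id` plus
#'   `beta`/`se` or `p`/`maf`/`n`).
#' @param qtl Data frame for the molecular side, same column contract.
#' @param p1,p2,p12 Prior probabilities (see [coloc_posteriors()]).
#' @param prior_sd_gwas,prior_sd_qtl Prior effect-size standard
#'   deviations for the two sides.
#' @return A `coloc_result` with an added `classification` element and
#'   `n_shared` variant count.
#' @export
coloc_test <- function(gwas, qtl, p1 = 1e-4, p2 = 1e-4, p12 = 1e-5,
                       prior_sd_gwas = 0.15, prior_sd_qtl = 0.15) {
  shared <- intersect(gwas$variant_id, qtl$variant_id)
  if (!length(shared)) stopf("no shared variants between the two traits")
  g <- gwas[match(shared, gwas$variant_id), ]
  q <- qtl[match(shared, qtl$variant_id), ]
  mk_abf <- function(d, W) {
    if (all(c("beta", "se") %in% names(d)) && !anyNA(d$se))
      single_variant_abf(d$beta, d$se, W)
    else if (all(c("p", "maf", "n") %in% names(d)))
      abf_from_pvalues(d$p, d$maf, d$n, W)
    else stopf("need beta/se or p/maf/n columns")
  }
  a1 <- setNames(mk_abf(g, prior_sd_gwas), shared)
  a2 <- setNames(mk_abf(q, prior_sd_qtl), shared)
  res <- coloc_posteriors(a1, a2, p1, p2, p12)
  res$n_shared <- length(shared)
  res$classification <- classify_coloc(res)
  res
}
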