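# Planted-truth phenotype simulation: gene expression (Gaussian) and
# histone-peak activity (negative-binomial counts with a genotype effect
# on the log mean).

#' Gene annotation for the simulated chromosome
#'
#' Genes are evenly spaced along the simulated chromosome with a 10 kb
#' span starting at the TSS.
#' @param config A [sim_config()].
#' @return Data frame with columns `feature_id`, `chrom`, `start`, `end`,
#'   `tss`, `kind`.
#' @export
sim_gene_annot <- function(config) {
  L <- as.numeric(config$n_variants) * config$variant_spacing
  tss <- as.integer(round(L * as.numeric(seq_len(config$n_genes)) /
                            (config$n_genes + 1)))
  data.frame(feature_id = sprintf("gene%04d", seq_len(config$n_genes)),
             chrom = config$chrom, start = tss, end = tss + 10000L,
             tss = tss, kind = "gene", stringsAsFactors = FALSE)
}

#' Peak annotation for the simulated chromosome
#'
#' Peaks (1 kb intervals, matching the ~0.5-1 kb widths typical of
#' histone-mark peaks) are placed 25 kb downstream of gene TSSs, cycling
#' through genes when there are more peaks than genes, so that a shared
#' causal variant can fall inside both a peak's 10 kb cis window and the
#' paired gene's 1 Mb window.
#' @param config A [sim_config()].
#' @return Data frame with columns `feature_id`, `chrom`, `start`, `end`,
#'   `kind`, and `near_gene` (the gene each peak sits next to).
#' @export
sim_peak_annot <- function(config) {
  genes <- sim_gene_annot(config)
  i <- seq_len(config$n_peaks)
  gi <- ((i - 1L) %% config$n_genes) + 1L
  round_k <- ((i - 1L) %/% config$n_genes) + 1L
  start <- genes$tss[gi] + 25000L + 4000L * (round_k - 1L)
  data.frame(feature_id = sprintf("peak%04d", i), chrom = config$chrom,
             start = start, end = start + 1000L, kind = "peak",
             near_gene = genes$feature_id[gi], stringsAsFactors = FALSE)
}

#' Plant causal variants and effect sizes for a feature set
#'
#' A configurable fraction of features receives one cis causal variant,
#' drawn uniformly from the variants inside the feature's cis window
#' (1 Mb of the TSS for genes; 10 kb beyond each peak end for peaks), and
#' a standardized effect size. Features without a planted effect are pure
#' noise downstream.
#'
#' @param genotypes A [genotype_matrix()] (the variant universe).
#' @param annot Feature annotation as from [sim_gene_annot()] /
#'   [sim_peak_annot()].
#' @param config A [sim_config()].
#' @param kind `"gene"` or `"peak"` (sets the cis-window rule).
#' @param forced_causal Optional named character vector
#'   (`feature_id -> variant_id`) overriding the causal variant of
#'   specific features; the variant must lie inside the feature's window.
#' @return Object of class `planted_truth`: list with `annot`, `kind`,
#'   and `truth` (data frame `feature_id`, `causal_variant`, `beta`).
#' @export
plant_truth <- function(genotypes, annot, config, kind = c("gene", "peak"),
                        forced_causal = NULL) {
  kind <- match.arg(kind)
  va <- genotypes$annot
  seed_k <- config$seed + if (kind == "gene") 101L else 202L
  truth <- with_seed(seed_k, {
    planted <- runif(nrow(annot)) < config$fraction_features_with_qtl
    causal <- rep(NA_character_, nrow(annot))
    beta <- rep(0, nrow(annot))
    for (i in which(planted)) {
      w <- cis_window(annot[i, ], kind)
      inside <- va$chrom == w$chrom & va$pos >= w$start &
        (if (kind == "gene") va$pos <= w$end else va$pos < w$end)
      if (!any(inside)) next
      causal[i] <- sample(va$variant_id[inside], 1L)
      beta[i] <- if (!is.null(config$effect_size))
        sample(c(-1, 1), 1L) * config$effect_size
      else rnorm(1L, 0, config$effect_size_sd)
    }
    data.frame(feature_id = annot$feature_id, causal_variant = causal,
               beta = beta, stringsAsFactors = FALSE)
  })
  if (!is.null(forced_causal)) {
    for (fid in names(forced_causal)) {
      i <- match(fid, truth$feature_id)
      if (is.na(i)) stopf("forced_causal names unknown feature '%s'", fid)
      v <- forced_causal[[fid]]
      j <- match(v, va$variant_id)
      if (is.na(j)) stopf("forced causal variant '%s' not in genotypes", v)
      w <- cis_window(annot[i, ], kind)
      if (va$pos[j] < w$start || va$pos[j] > w$end)
        stopf("forced causal '%s' outside cis window of '%s'", v, fid)
      truth$causal_variant[i] <- v
      if (truth$beta[i] == 0)
        truth$beta[i] <- config$effect_size %||% config$effect_size_sd
    }
  }
  structure(list(annot = annot, kind = kind, truth = truth),
            class = "planted_truth")
}

#' Simulate cohort covariates
#'
#' A sex indicator plus `n_pc` continuous scores standing in for genotype
#' principal components / expression factors.
#' @param n Number of samples.
#' @param n_pc Number of continuous covariates.
#' @param seed Integer seed.
#' @return An `n x (1 + n_pc)` numeric matrix.
#' @export
simulate_covariates <- function(n, n_pc = 2L, seed = 1L) {
  with_seed(seed, {
    m <- cbind(sex = rbinom(n, 1, 0.5),
               matrix(rnorm(n * n_pc), n,
                      dimnames = list(NULL, paste0("pc", seq_len(n_pc)))))
    m
  })
}

# Shared core: standardized-dosage genetic values for planted features.
genetic_values <- function(genotypes, truth) {
  n <- nrow(genotypes$dosages)
  gv <- matrix(0, n, nrow(truth$truth))
  planted <- which(!is.na(truth$truth$causal_variant))
  if (length(planted)) {
    miss <- setdiff(truth$truth$causal_variant[planted],
                    colnames(genotypes$dosages))
    if (length(miss))
      stopf("causal variant(s) absent from genotypes: %s",
            paste(utils::head(miss, 5), collapse = ", "))
    for (i in planted) {
      g <- genotypes$dosages[, truth$truth$causal_variant[i]]
      s <- sd(g)
      if (s > 0) gv[, i] <- truth$truth$beta[i] * (g - mean(g)) / s
    }
  }
  gv
}

#' Simulate gene expression with planted cis effects
#'
#' Feature value = planted beta x standardized dosage + covariate
#' loadings + standard normal noise.
#'
#' @param genotypes A [genotype_matrix()] for one cohort.
#' @param truth A [plant_truth()] result of kind `"gene"`.
#' @param config A [sim_config()].
#' @param covariates Optional sample x covariate matrix; each feature
#'   receives random loadings (sd `covariate_sd`) on it.
#' @param covariate_sd Loading scale for covariates.
#' @param seed Seed for the noise draw (defaults to a cohort-independent
#'   derivation from `config$seed` and the sample ids).
#' @return A [feature_matrix()] of expression values.
#' @export
simulate_expression <- function(genotypes, truth, config, covariates = NULL,
                                covariate_sd = 0.3, seed = NULL) {
  stopifnot(inherits(truth, "planted_truth"))
  n <- nrow(genotypes$dosages)
  seed <- seed %||%
    ((config$seed * 17L + n * 7L + 307L) %% 2147483646L + 1L)
  gv <- genetic_values(genotypes, truth)
  vals <- with_seed(seed, {
    v <- gv + matrix(rnorm(n * ncol(gv)), n)
    if (!is.null(covariates)) {
      load <- matrix(rnorm(ncol(covariates) * ncol(gv), 0, covariate_sd),
                     ncol(covariates))
      v <- v + as.matrix(covariates) %*% load
    }
    v
  })
  rownames(vals) <- rownames(genotypes$dosages)
  colnames(vals) <- truth$truth$feature_id
  feature_matrix(vals, truth$annot)
}

#' Simulate histone-peak read counts with planted cis effects
#'
#' Negative-binomial counts whose log mean carries the genotype effect:
#' `mu = baseline_mean * exp(beta * standardized dosage + covariate
#' terms)`. The default baseline keeps retained peaks above the
#' mean-count-20 inclusion rule by construction. As `dispersion -> 0` the
#' counts approach Poisson.
#'
#' @inheritParams simulate_expression
#' @param truth A [plant_truth()] result of kind `"peak"`.
#' @param baseline_mean Baseline expected read count per peak.
#' @param dispersion Negative-binomial dispersion (`size = 1/dispersion`).
#' @return A [feature_matrix()] of integer counts.
#' @export
simulate_peaks <- function(genotypes, truth, config, covariates = NULL,
                           covariate_sd = 0.1, baseline_mean = 60,
                           dispersion = 0.2, seed = NULL) {
  stopifnot(inherits(truth, "planted_truth"))
  if (dispersion < 0) stopf("dispersion must be >= 0")
  n <- nrow(genotypes$dosages)
  seed <- seed %||%
    ((config$seed * 23L + n * 11L + 509L) %% 2147483646L + 1L)
  eta <- genetic_values(genotypes, truth)
  vals <- with_seed(seed, {
    if (!is.null(covariates)) {
      load <- matrix(rnorm(ncol(covariates) * ncol(eta), 0, covariate_sd),
                     ncol(covariates))
      eta <- eta + as.matrix(covariates) %*% load
    }
    mu <- baseline_mean * exp(eta)
    cnt <- if (dispersion == 0) stats::rpois(length(mu), mu)
    else rnbinom(length(mu), mu = mu, size = 1 / dispersion)
    matrix(cnt, n)
  })
  rownames(vals) <- rownames(genotypes$dosages)
  colnames(vals) <- truth$truth$feature_id
  feature_matrix(vals, truth$annot)
}

#' Simulate multi-tissue sharing profiles (m-values)
#'
#' For each feature, a tissue-sharing class is planted (`shared`: effect
#' present in >= 38 of 43 non-liver tissues; `liver_specific`: < 5;
#' `neither`: otherwise) and per-tissue posterior probabilities are
#' emitted as beta-distributed noise around the 0/1 sharing indicator.
#'
#' @param feature_ids Character vector of feature ids.
#' @param n_tissues Number of non-liver tissues profiled.
#' @param class_probs Named probabilities for the three planted classes.
#' @param concentration Beta shape parameter controlling how tightly
#'   m-values hug their indicator.
#' @param seed Integer seed.
#' @return List with `profiles` (features x tissues matrix of m-values)
#'   and `class` (planted class per feature).
#' @export
simulate_sharing_profiles <- function(feature_ids, n_tissues = 43L,
                                      class_probs = c(shared = 0.25,
                                                      liver_specific = 0.25,
                                                      neither = 0.5),
                                      concentration = 60, seed = 1L) {
  with_seed(seed, {
    cls <- sample(names(class_probs), length(feature_ids), replace = TRUE,
                  prob = class_probs)
    prof <- t(vapply(cls, function(cl) {
      k <- switch(cl,
                  shared = sample(38:n_tissues, 1L),
                  liver_specific = sample(0:4, 1L),
                  neither = sample(5:37, 1L))
      ind <- sample(rep(c(1L, 0L), c(k, n_tissues - k)))
      ifelse(ind == 1L, rbeta(n_tissues, concentration, 1),
             rbeta(n_tissues, 1, concentration))
    }, numeric(n_tissues)))
    rownames(prof) <- feature_ids
    colnames(prof) <- sprintf("tissue%02d", seq_len(n_tissues))
    list(profiles = prof, class = setNames(cls, feature_ids))
  })
}
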