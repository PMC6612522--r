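# End-to-end study wrapper over the synthetic generator: simulate three
# cohorts, scan, meta-analyze, colocalize, integrate, enrich. Primarily
# a demonstration and smoke-test harness; each stage is the exported
# function documented in its own module.

#' Run the full integrative pipeline on synthetic data
#'
#' Simulates a multi-cohort study from a [sim_config()] (expression in
#' every cohort, histone peaks in cohort 1 with a fraction of peaks
#' sharing a gene's causal variant), then runs: per-cohort lead scans
#' with beta-approximated permutation p-values and BH correction;
#' cross-cohort weighted-z meta-analysis with the permutation-based
#' empirical FDR; GWAS simulation and ABF colocalization at loci anchored
#' on significant genes; promoter-capture interaction merging and
#' peak-to-gene assignment; LD-based co-regulation and GWAS-peak
#' linking; and matched-SNP overlap enrichment of lead eQTLs in peaks.
#'
#' @param config A [sim_config()].
#' @param n_perm Permutations per feature for adjusted p-values.
#' @param q FDR level for all significance calls.
#' @param coreg_fraction Fraction of planted peaks forced to share the
#'   causal variant of their neighbouring planted gene.
#' @param n_gwas_loci Number of GWAS traits simulated (anchored on the
#'   first significant genes; half shared-causal, half distinct).
#' @param n_gwas GWAS sample size.
#' @param h2_locus Locus heritability of each simulated GWAS trait.
#' @param gwas_method `"analytic"` or `"cohort"` (see [simulate_gwas()]).
#' @param n_null_sets Matched null sets for the enrichment stage.
#' @param seed Master seed for the analysis stages (the generator itself
#'   is driven by `config$seed`).
#' @return A list with elements `truth` (planted truth tables),
#'   `cohorts`, `leads` (per-cohort lead tables), `meta`
#'   (`fdr_calibration` plus lead table), `eqtl_significant`,
#'   `hqtl` (lead table and calibration), `coloc` (per-locus results),
#'   `interactions` (merged calls and peak-gene map), `coregulation`,
#'   `gwas_links`, and `enrichment`.
#' @export
run_study <- function(config = sim_config(), n_perm = 200L, q = 0.05,
                      coreg_fraction = 0.6, n_gwas_loci = 4L,
                      n_gwas = 50000L, h2_locus = 0.001,
                      gwas_method = c("analytic", "cohort"),
                      n_null_sets = 100L, seed = config$seed) {
  gwas_method <- match.arg(gwas_method)
  n_cohorts <- length(config$n_samples_per_cohort)

  genos <- lapply(seq_len(n_cohorts), function(c)
    simulate_genotypes(config, c))
  common <- Reduce(intersect, lapply(genos, function(g) g$annot$variant_id))
  ref <- genos[[1]]
  ref_common <- genotype_matrix(
    ref$dosages[, common, drop = FALSE],
    ref$annot[ref$annot$variant_id %in% common, ])
  attr(ref_common, "sim") <- attr(ref, "sim")

  genes <- sim_gene_annot(config)
  peaks <- sim_peak_annot(config)
  truth_genes0 <- plant_truth(ref_common, genes, config, "gene")

  # co-regulated pairs: a planted peak and its neighbouring planted gene
  # share one causal variant drawn from the peak's 10 kb window (always
  # inside the gene's 1 Mb window by construction)
  shared_causal <- with_seed(seed + 5L, {
    tg <- truth_genes0$truth
    cand <- peaks$feature_id[!is.na(tg$causal_variant[
      match(peaks$near_gene, tg$feature_id)])]
    take <- cand[runif(length(cand)) < coreg_fraction]
    fc <- vapply(take, function(pid) {
      pa <- peaks[peaks$feature_id == pid, ]
      vids <- window_variants(ref_common, cis_window(pa, "peak"))
      if (!length(vids)) NA_character_
      else if (length(vids) == 1) vids else sample(vids, 1L)
    }, character(1))
    fc[!is.na(fc)]
  })
  forced_genes <- setNames(
    unname(shared_causal),
    peaks$near_gene[match(names(shared_causal), peaks$feature_id)])
  forced_genes <- forced_genes[!duplicated(names(forced_genes))]
  truth_genes <- plant_truth(ref_common, genes, config, "gene",
                             forced_causal = forced_genes)
  truth_peaks <- plant_truth(ref_common, peaks, config, "peak",
                             forced_causal = shared_causal)

  cohorts <- lapply(seq_len(n_cohorts), function(c) {
    g <- genos[[c]]
    n <- nrow(g$dosages)
    cov <- simulate_covariates(n, seed = config$seed + 900L + c)
    rownames(cov) <- rownames(g$dosages)
    gc <- genotype_matrix(
      g$dosages[, intersect(colnames(g$dosages), common), drop = FALSE],
      g$annot[g$annot$variant_id %in% common, ])
    expr <- simulate_expression(gc, truth_genes, config, covariates = cov)
    list(genotypes = gc, covariates = cov,
         phenotype = normalize_phenotypes(expr, log_transform = FALSE))
  })

  # per-cohort lead scans + BH
  leads <- lapply(seq_len(n_cohorts), function(c)
    scan_leads(cohorts[[c]]$genotypes, cohorts[[c]]$phenotype,
               cohorts[[c]]$covariates, kind = "gene", n_perm = n_perm,
               seed = seed + 11L * c))
  bh_sig <- lapply(leads, function(l)
    bh_fdr(setNames(l$adjusted_p, l$feature_id), q))

  # meta-analysis with permutation-based empirical FDR
  meta_true <- meta_scan(cohorts, kind = "gene", keep_records = TRUE)
  meta_null <- meta_scan(cohorts, kind = "gene",
                         permute_seed = seed + 41L)
  cal <- empirical_fdr(
    setNames(meta_true$leads$min_p, meta_true$leads$feature_id),
    meta_null$leads$min_p, q)
  eqtl_sig <- cal$significant
  eqtl_leads <- meta_true$leads[meta_true$leads$feature_id %in% eqtl_sig, ]

  # hQTL mapping on cohort 1 counts
  peaks_fm <- simulate_peaks(cohorts[[1]]$genotypes, truth_peaks, config,
                             covariates = cohorts[[1]]$covariates)
  kept_peaks <- filter_peaks(peaks_fm)
  peaks_norm <- normalize_phenotypes(subset_features(peaks_fm, kept_peaks))
  hco <- list(list(genotypes = cohorts[[1]]$genotypes,
                   phenotype = peaks_norm,
                   covariates = cohorts[[1]]$covariates))
  hq_true <- meta_scan(hco, kind = "peak")
  hq_null <- meta_scan(hco, kind = "peak", permute_seed = seed + 43L)
  hq_cal <- empirical_fdr(
    setNames(hq_true$leads$min_p, hq_true$leads$feature_id),
    hq_null$leads$min_p, q)
  hqtl_leads <- hq_true$leads[hq_true$leads$feature_id %in%
                                hq_cal$significant, ]

  # GWAS simulation + colocalization at loci anchored on significant genes
  tg <- truth_genes$truth
  anchor_genes <- intersect(eqtl_sig,
                            tg$feature_id[!is.na(tg$causal_variant)])
  anchor_genes <- utils::head(anchor_genes, n_gwas_loci)
  coloc_rows <- list()
  for (i in seq_along(anchor_genes)) {
    gid <- anchor_genes[i]
    shared <- i %% 2L == 1L
    gw <- simulate_gwas(ref_common,
                        tg$causal_variant[tg$feature_id == gid],
                        n_gwas = n_gwas, h2_locus = h2_locus,
                        shared = shared, method = gwas_method,
                        seed = seed + 600L + i)
    loci <- define_loci(gw)
    if (is.null(loci) || !nrow(loci)) next
    rec <- meta_true$records[[gid]]
    va <- ref_common$annot
    qtl <- data.frame(variant_id = rec$variant_id, p = rec$p,
                      maf = va$maf[match(rec$variant_id, va$variant_id)],
                      n = rec$n_total)
    res <- coloc_test(gw, qtl)
    coloc_rows[[length(coloc_rows) + 1L]] <- data.frame(
      locus_id = loci$locus_id[1], gene_id = gid,
      truth_shared = shared, n_shared = res$n_shared,
      t(res$pp), power = res$power, ratio = res$ratio,
      classification = res$classification, stringsAsFactors = FALSE)
  }
  coloc_tab <- do.call(rbind, coloc_rows) %||% data.frame()

  # interactions: two-resolution merge + peak-to-gene assignment
  calls <- simulate_interactions(genes, peaks, config)
  merged <- merge_resolutions(
    calls[calls$resolution == "1frag", , drop = FALSE],
    calls[calls$resolution == "4frag", , drop = FALSE])
  peak_gene_map <- assign_peak_genes(peaks, merged)

  coreg <- coregulated_pairs(eqtl_leads[, c("feature_id", "lead_variant")],
                             hqtl_leads[, c("feature_id", "lead_variant")],
                             genes, peaks, ref_common, mhc = NULL)
  links <- if (length(coloc_rows)) {
    all_loci <- do.call(rbind, lapply(seq_along(anchor_genes), function(i) {
      gw <- simulate_gwas(ref_common,
                          tg$causal_variant[tg$feature_id ==
                                              anchor_genes[i]],
                          n_gwas = n_gwas, h2_locus = h2_locus,
                          shared = i %% 2L == 1L, method = gwas_method,
                          seed = seed + 600L + i)
      define_loci(gw)
    }))
    gwas_hqtl_links(all_loci, hqtl_leads[, c("feature_id",
                                             "lead_variant")],
                    peaks, ref_common, mhc = NULL)
  } else data.frame()

  # enrichment of significant lead eQTLs in histone peaks
  enrich <- NULL
  if (nrow(eqtl_leads) >= 3) {
    snp_ann <- simulate_snp_annotations(ref_common, genes)
    targets <- unique(eqtl_leads$lead_variant)
    # a 500-variant synthetic panel is far sparser than a genome-wide
    # SNP pool, so the demo matches with proportionally wider tolerances
    nulls <- sample_matched_snps(
      targets, snp_ann,
      match_criteria(maf_tolerance = 0.1, gene_density_tolerance = 0.5,
                     distance_tolerance = 2, buddies_tolerance = 1,
                     n_sets = n_null_sets),
      seed = seed + 77L)
    va <- ref_common$annot
    tpos <- data.frame(chrom = va$chrom[match(targets, va$variant_id)],
                       pos = va$pos[match(targets, va$variant_id)])
    null_pos <- lapply(nulls, function(s)
      data.frame(chrom = va$chrom[match(s, va$variant_id)],
                 pos = va$pos[match(s, va$variant_id)]))
    enrich <- overlap_enrichment(
      tpos, peaks[, c("chrom", "start", "end")], null_pos)
  }

  # tissue-sharing classification of significant eQTLs
  sharing <- NULL
  if (length(eqtl_sig)) {
    prof <- simulate_sharing_profiles(eqtl_sig, seed = seed + 88L)
    sharing <- list(
      planted = prof$class,
      classified = vapply(eqtl_sig, function(g)
        classify_sharing(prof$profiles[g, ]), character(1)))
  }

  list(truth = list(genes = truth_genes$truth, peaks = truth_peaks$truth),
       cohorts = cohorts,
       leads = leads, bh_significant = bh_sig,
       meta = list(leads = meta_true$leads, calibration = cal),
       eqtl_significant = eqtl_sig,
       hqtl = list(leads = hqtl_leads, calibration = hq_cal),
       coloc = coloc_tab,
       interactions = list(calls = calls, merged = merged,
                           peak_gene_map = peak_gene_map),
       coregulation = coreg, gwas_links = links,
       enrichment = enrich, sharing = sharing)
}
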