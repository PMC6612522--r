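# Matched-null construction, overlap enrichment, tissue-sharing
# classification, and permutation p-values for set comparisons.

#' Classify an eQTL's tissue-sharing profile
#'
#' Counts non-liver tissues with posterior probability (m-value) above
#' `m_min`: at least `shared_min` tissues -> `"shared"`; fewer than
#' `specific_max` -> `"liver_specific"`; otherwise `"neither"`. The
#' defaults reflect a 43-tissue profile with quartile cutoffs at 38 and
#' 5.
#'
#' @param profile Numeric vector of per-tissue posteriors in `[0, 1]`.
#' @param m_min Posterior threshold for counting a tissue.
#' @param shared_min Minimum tissue count for `"shared"`.
#' @param specific_max Strict upper tissue count for `"liver_specific"`.
#' @return One of `"shared"`, `"liver_specific"`, `"neither"`.
#' @export
classify_sharing <- function(profile, m_min = 0.9, shared_min = 38L,
                             specific_max = 5L) {
  if (any(profile < 0 | profile > 1))
    stopf("m-values must lie in [0, 1]")
  n_above <- sum(profile > m_min)
  if (n_above >= shared_min) "shared"
  else if (n_above < specific_max) "liver_specific"
  else "neither"
}

#' Matching criteria for null-SNP sampling
#'
#' @param maf_tolerance Absolute MAF tolerance (percentage points / 100).
#' @param gene_density_tolerance Relative gene-density tolerance.
#' @param distance_tolerance Relative nearest-gene-distance tolerance.
#' @param buddies_tolerance Relative LD-buddy-count tolerance.
#' @param n_sets Number of matched sets to draw.
#' @return List of class `match_criteria`.
#' @export
match_criteria <- function(maf_tolerance = 0.05,
                           gene_density_tolerance = 0.05,
                           distance_tolerance = 0.5,
                           buddies_tolerance = 0.5,
                           n_sets = 1000L) {
  tol <- c(maf_tolerance, gene_density_tolerance, distance_tolerance,
           buddies_tolerance)
  if (any(tol <= 0)) stopf("tolerances must be positive")
  if (n_sets < 1) stopf("n_sets must be >= 1")
  structure(list(maf_tolerance = maf_tolerance,
                 gene_density_tolerance = gene_density_tolerance,
                 distance_tolerance = distance_tolerance,
                 buddies_tolerance = buddies_tolerance,
                 n_sets = as.integer(n_sets)), class = "match_criteria")
}

# Eligibility of pool variants for one target under (possibly widened)
# criteria. MAF is matched absolutely, the rest relatively.
matched_pool <- function(target_row, annotation, criteria, widen = 1) {
  a <- annotation
  rel_ok <- function(x, t, tol) {
    lo <- t * (1 - tol * widen)
    hi <- t * (1 + tol * widen)
    x >= min(lo, hi) & x <= max(lo, hi)
  }
  ok <- abs(a$maf - target_row$maf) <=
    criteria$maf_tolerance * widen &
    rel_ok(a$gene_density, target_row$gene_density,
           criteria$gene_density_tolerance) &
    rel_ok(a$dist_nearest_gene, target_row$dist_nearest_gene,
           criteria$distance_tolerance) &
    rel_ok(a$ld_buddies, target_row$ld_buddies,
           criteria$buddies_tolerance) &
    a$variant_id != target_row$variant_id
  a$variant_id[ok]
}

#' Draw matched null SNP sets
#'
#' For each target variant, samples null variants matched on MAF
#' (absolute tolerance), gene density, distance to nearest gene, and
#' LD-buddy count (relative tolerances), producing `n_sets` sets of
#' `|targets|` variants each. Sampling is without replacement within a
#' set and never returns the target itself. Targets with an empty
#' eligible pool trigger a stepwise x1.5 widening of the tolerances (up
#' to 3 rounds, with a warning) before erroring.
#'
#' @param targets Character vector of target variant ids.
#' @param annotation Annotation table from [simulate_snp_annotations()]
#'   covering targets and the candidate pool.
#' @param criteria A [match_criteria()].
#' @param seed Integer seed.
#' @return List of `n_sets` character vectors, each of length
#'   `length(targets)`, with attribute `"pool_sizes"`.
#' @export
sample_matched_snps <- function(targets, annotation,
                                criteria = match_criteria(), seed = 1L) {
  miss <- setdiff(targets, annotation$variant_id)
  if (length(miss))
    stopf("unannotated target(s): %s", paste(utils::head(miss, 5),
                                             collapse = ", "))
  pools <- vector("list", length(targets))
  for (i in seq_along(targets)) {
    trow <- annotation[annotation$variant_id == targets[i], ]
    widen <- 1
    pool <- matched_pool(trow, annotation, criteria, widen)
    round <- 0L
    while (!length(pool) && round < 3L) {
      round <- round + 1L
      widen <- widen * 1.5
      warnf("no matched pool for '%s'; widening tolerances x%.2f",
            targets[i], widen)
      pool <- matched_pool(trow, annotation, criteria, widen)
    }
    if (!length(pool))
      stopf("no eligible matched variant for target '%s'", targets[i])
    pools[[i]] <- pool
  }
  sets <- with_seed(seed, {
    lapply(seq_len(criteria$n_sets), function(s) {
      used <- character(0)
      out <- character(length(targets))
      # fill scarcest pools first to reduce exhaustion
      for (i in order(lengths(pools))) {
        avail <- setdiff(pools[[i]], used)
        if (!length(avail))
          stopf("pool exhausted for target '%s' in set %d", targets[i], s)
        out[i] <- if (length(avail) == 1) avail else sample(avail, 1L)
        used <- c(used, out[i])
      }
      out
    })
  })
  attr(sets, "pool_sizes") <- lengths(pools)
  sets
}

#' Overlap enrichment of a target set against matched nulls
#'
#' Counts targets overlapping at least one feature region, compares with
#' the overlaps of matched null sets via a one-sided (greater) Fisher's
#' exact test on the 2x2 table (overlap / non-overlap x target /
#' null-aggregate), and also reports the empirical permutation p
#' ([permutation_proportion_test()]), since the table aggregation of
#' null sets is a convention rather than a uniquely defined test.
#'
#' @param targets Data frame of target positions (`chrom`, `pos`) or
#'   regions (`chrom`, `start`, `end`).
#' @param features Data frame of feature regions (`chrom`, `start`,
#'   `end`), half-open.
#' @param null_sets List of data frames shaped like `targets`.
#' @return List: `observed`, `expected` (mean null overlap),
#'   `odds_ratio` (Haldane-corrected when a cell is 0, flagged by
#'   `or_corrected`), `fisher_p`, `empirical_p`, `table`.
#' @export
overlap_enrichment <- function(targets, features, null_sets) {
  count_overlap <- function(d) {
    if (!nrow(d)) return(0L)
    if ("pos" %in% names(d)) {
      s <- d$pos
      e <- d$pos + 1L
    } else {
      s <- d$start
      e <- d$end
    }
    hit <- vapply(seq_along(s), function(i)
      any(features$chrom == d$chrom[i] & features$start < e[i] &
            s[i] < features$end), logical(1))
    sum(hit)
  }
  obs <- count_overlap(targets)
  n_t <- nrow(targets)
  null_counts <- vapply(null_sets, count_overlap, integer(1))
  null_sizes <- vapply(null_sets, nrow, integer(1))
  tab <- matrix(c(obs, n_t - obs,
                  sum(null_counts), sum(null_sizes) - sum(null_counts)),
                2, 2, byrow = TRUE,
                dimnames = list(c("target", "null"),
                                c("overlap", "no_overlap")))
  fp <- fisher.test(tab, alternative = "greater")$p.value
  corrected <- any(tab == 0)
  t2 <- if (corrected) tab + 0.5 else tab
  or <- (t2[1, 1] * t2[2, 2]) / (t2[1, 2] * t2[2, 1])
  list(observed = obs, expected = mean(null_counts), odds_ratio = or,
       or_corrected = corrected, fisher_p = fp,
       empirical_p = permutation_proportion_test(obs, n_t, null_counts),
       table = tab)
}

#' Permutation p-value for an observed count against null counts
#'
#' Add-one convention: `p = (1 + #\{null >= observed\}) / (1 + #null)`,
#' so the p-value can never be exactly 0; an observation exceeding all
#' 999 of 999 nulls yields 0.001.
#'
#' @param observed_count Observed count.
#' @param set_size Size of the observed set (unused by the statistic,
#'   kept for interface symmetry / sanity checking).
#' @param null_counts Integer vector of null counts.
#' @return Permutation p-value in `(0, 1]`.
#' @export
permutation_proportion_test <- function(observed_count, set_size = NULL,
                                        null_counts) {
  if (!length(null_counts)) stopf("null_counts must be non-empty")
  (1 + sum(null_counts >= observed_count)) / (1 + length(null_counts))
}

#' Random size-matched region sets
#'
#' Draws `n_sets` region sets preserving the multiset of target region
#' lengths; each region is placed uniformly on a chromosome chosen with
#' probability proportional to its length, avoiding optional excluded
#' intervals and never exceeding chromosome bounds.
#'
#' @param targets Data frame of regions (`chrom`, `start`, `end`).
#' @param genome Data frame of chromosome sizes (`chrom`, `length`).
#' @param n_sets Number of sets.
#' @param seed Integer seed.
#' @param exclude Optional data frame of excluded regions (`chrom`,
#'   `start`, `end`).
#' @return List of `n_sets` region data frames.
#' @export
random_region_sets <- function(targets, genome, n_sets = 1000L, seed = 1L,
                               exclude = NULL) {
  lens <- targets$end - targets$start
  if (any(lens <= 0)) stopf("target regions must have positive length")
  with_seed(seed, {
    lapply(seq_len(n_sets), function(s) {
      chrom <- character(length(lens))
      start <- integer(length(lens))
      for (i in seq_along(lens)) {
        for (try in seq_len(200L)) {
          ok_chr <- genome[genome$length >= lens[i], , drop = FALSE]
          if (!nrow(ok_chr))
            stopf("region of length %d exceeds every chromosome", lens[i])
          ci <- sample.int(nrow(ok_chr), 1L, prob = ok_chr$length)
          st <- sample.int(ok_chr$length[ci] - lens[i] + 1L, 1L) - 1L
          clash <- !is.null(exclude) &&
            any(exclude$chrom == ok_chr$chrom[ci] &
                  exclude$start < st + lens[i] & st < exclude$end)
          if (!clash) {
            chrom[i] <- ok_chr$chrom[ci]
            start[i] <- st
            break
          }
          if (try == 200L)
            stopf("could not place a region outside excluded intervals")
        }
      }
      data.frame(chrom = chrom, start = start, end = start + lens,
                 stringsAsFactors = FALSE)
    })
  })
}
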