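---
title: "Methods: integrative QTL mapping, meta-analysis, and GWAS colocalization"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: integrative QTL mapping, meta-analysis, and GWAS colocalization}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtlweave)
```

# Overview

`qtlweave` implements an integrative fine-mapping workflow for tissue
molecular QTL studies: cis scans of gene expression and histone-peak
activity with permutation-calibrated significance, cross-cohort
meta-analysis with a permutation-based empirical FDR, Bayesian
colocalization against GWAS summary statistics, LD-based linking of
regulatory elements to genes and traits, and promoter-capture
interaction integration. This vignette documents the statistical models,
the tunable parameters and their defaults, the synthetic-data generator
used for validation, and the numerical and design choices made where
more than one reasonable convention exists.

# Phenotype preparation

Expression enters as estimated read counts and TPM; genes are kept when
count > 6 and TPM > 0.1 in at least 10% of subjects
(`filter_expressed()`). Histone peaks are kept when their cross-sample
mean read count is at least 20 (`filter_peaks()`). Retained phenotypes
are normalized in three steps (`normalize_phenotypes()`): natural log
with a pseudocount of 1; quantile normalization *between individuals*
over all features (each individual acquires the same empirical
distribution); and a per-feature rank-based inverse-normal transform to
Blom scores, `qnorm((rank - 0.375) / (n + 0.25))`.

Two numerical points deserve note. First, between-individual quantile
normalization maps every individual onto one shared value grid, so
cross-individual ties within a feature are expected rather than
exceptional; ranks are made strict by breaking ties with the
pre-normalization values (and sample order as a last resort), which
keeps the transform invariant under monotone transformations of the
input and makes every output feature an exact permutation of one
normal-score vector. Second, a feature that is constant on input is
excluded outright: the between-individual step would otherwise lend it
spurious variation with no rank information behind it.

# Cis association scan

The cis window is 1 Mb either side of the TSS for genes (closed
interval) and 10 kb beyond each end of the peak interval for histone
peaks (half-open), clipped at zero (`cis_window()`). A variant-feature
pair on the same chromosome is *trans* when more than 5 Mb from the
anchor — strictly more, so a pair at exactly 5 Mb is cis; the anchor is
the TSS for genes and the nearest interval edge for peaks
(`trans_pairs()`).

Nominal association (`nominal_scan()`) residualizes both dosage and
phenotype on the covariates plus intercept and tests the Pearson
correlation r with `t = r sqrt(df / (1 - r^2))` on `df = n - 2 - k`
degrees of freedom (k covariates). Monomorphic variants are skipped and
reported; a constant phenotype is an error. Underflowing p-values are
clamped to the smallest positive double rather than zero so that
downstream log-space work stays defined.

Histone peaks are scanned with the identical linear machinery on the
normalized total peak signal. Allele-specific read-count models can
squeeze more power out of small ChIP cohorts, but they need read-level
data that summary matrices do not carry; total-signal scanning keeps
the peak and gene pipelines symmetric and is the model the synthetic
counts actually follow.

## Permutation-adjusted p-values

`permutation_adjusted_p()` calibrates each feature's lead p-value: the
phenotype is permuted across samples (default 10,000 times; validation
runs use 150-2,000 to keep suites fast — the approximation quality is
checked explicitly at 2,000), the minimum nominal p over the window is
recorded per permutation, a Beta(a, b) distribution is fitted to the
permuted minima by maximum likelihood (method-of-moments
initialization, BFGS on log-shape parameters), and the adjusted p is
the fitted CDF at the observed minimum. If the fit fails the empirical
`(count + 1) / (n_perm + 1)` is reported instead. Covariates are held
fixed by permuting the *residualized* phenotype against residualized
genotypes; a `permute = "raw"` switch re-residualizes each permutation
for users who prefer permuting the raw phenotype (the two agree closely
whenever covariates are genuinely exogenous). Lead-variant ties break
by genomic position, then lexicographic id, so outputs are
deterministic.

# Meta-analysis and the empirical FDR

Per-cohort evidence combines by the sample-size weighted z-score
scheme (`stouffer_meta()`): `z_i = sign_i * Phi^-1(1 - p_i / 2)`,
`z = sum(sqrt(n_i) z_i) / sqrt(sum(n_i))`, meta p
`= 2 (1 - Phi(|z|))`. The formula is implemented directly (upper-tail
quantile/CDF calls, so tiny p-values keep full precision); a variant
missing from one cohort (e.g. dropped by its MAF filter) is combined
over the cohorts that retain it, with the total n recorded.

Genome-wide significance uses the permutation-based empirical FDR
(`empirical_fdr()`): with per-feature minimum meta p-values from the
observed scan (the *true* distribution) and from one scan of permuted
phenotypes per cohort (the *null* distribution), the threshold `z*` is
the largest observed minimum satisfying
`frac(null < z) / frac(true < z) <= q`. Features with true minimum
strictly below `z*` are significant. Three conventions were open and
are fixed as follows: the defining ratio rarely attains `q` exactly, so
the most permissive threshold with ratio at most `q` is used; both
"fraction below" comparisons are strict; and one permutation pass per
cohort is the default, with additional passes simply pooled into the
null list. Per-cohort lead p-values can instead be BH-corrected across
features (`bh_fdr()`), which is the within-cohort convention.

# Colocalization

GWAS loci are defined greedily from summary statistics
(`define_loci()`): repeatedly take the most significant unmasked
variant with p below 1e-6, emit the 2 Mb locus centered on it, and mask
all variants within 2 Mb of the lead. The masking radius is the full
locus width: a candidate any closer would found a region overlapping
the one just emitted, and the construction should yield one lead per
2 Mb region. Ties on p break by position.

Each locus is paired with genes whose TSS lies inside it
(`locus_feature_pairs()`; closed boundaries, so a TSS exactly on the
edge counts), either restricted to significant QTL genes or — as a
rescan mode — all expressed genes in the window. Per-variant Wakefield
log approximate Bayes factors (`single_variant_abf()`) use prior effect
standard deviation W = 0.15 for quantitative traits (0.2 recommended
for binary), and can be reconstructed from (p, MAF, N) when beta/SE are
unavailable (`abf_from_pvalues()`); beta/SE input is preferred when
both exist. `coloc_posteriors()` accumulates the five hypothesis sums
in log space with log-sum-exp; the two-distinct-variants term
`S1 * S2 - S12` is computed as a guarded log-difference that returns
-Inf (PP3 = 0) for a single-variant locus or on numerical ties. Priors
default to p1 = p2 = 1e-4, p12 = 1e-5. Classification
(`classify_coloc()`): testable only when `PP3 + PP4 > 0.8`; then
colocalized when `PP4 / (PP3 + PP4) > 0.9`, else distinct.

# Linking and interaction integration

Lead-variant LD is the squared Pearson correlation of dosages in a
designated reference panel (`ld_r2()`) — unphased, dosage-based, since
phase is not assumed. A gene with a significant eQTL and a peak with a
significant hQTL within 1 Mb of its TSS are putatively co-regulated
when their leads have `r^2 > 0.8` (strict) (`coregulated_pairs()`);
the same rule links peaks to GWAS locus leads (`gwas_hqtl_links()`).
All linking outputs drop signals in the MHC interval
(chr6:28,510,120-33,480,577, `mhc_interval()`), whose long-range LD
makes lead-variant identity unreliable.

Interaction calls at the two fragment resolutions merge by union,
removing any 4-fragment call whose other-end interval contains a
1-fragment call's other-end with the same bait gene
(`merge_resolutions()`). "Contains" means interval containment on the
other end with identical bait — the bait side is not compared, since
both resolutions bait the same promoters. Peaks map to every bait gene
whose call's other end overlaps the peak by at least 1 bp, half-open,
so touching intervals do not overlap (`assign_peak_genes()`).
Peak-to-TSS distance is 0 when the TSS lies inside the peak and the
gap to the nearest edge otherwise; that convention feeds both
`closer_gene_count()` (how many genes sit nearer to a peak than its
linked gene) and the pairing window.

# Enrichment and tissue sharing

`sample_matched_snps()` draws null variant sets matched per target on
MAF (absolute tolerance 0.05 — "±5%" is read as percentage points),
gene density (±5% relative), distance to nearest gene (±50% relative),
and LD-buddy count at `r^2 >= 0.5` (±50% relative), without replacement
within a set and never returning the target. A target with an empty
pool widens its tolerances stepwise by 1.5x, warning each time, up to
three rounds before erroring. `overlap_enrichment()` reports the
one-sided Fisher p on the 2x2 table aggregating all null sets
(overlap/non-overlap by target/null), the Haldane-corrected odds ratio
when a cell is zero, and — because the table aggregation is a
convention, not a uniquely defined test — the empirical add-one
permutation p alongside (`permutation_proportion_test()`,
`p = (1 + #{null >= obs}) / (1 + #null)`, so 1,000 sets bottom out at
0.001, never 0). `random_region_sets()` provides length-preserving
random region placement for region-level backgrounds.

Multi-tissue sharing of an eQTL is classified from per-tissue posterior
probabilities (m-values) over 43 non-liver tissues
(`classify_sharing()`): at least 38 tissues above 0.9 is *shared*,
fewer than 5 is *liver-specific* (strictly fewer — exactly 5 is
*neither*).

# The synthetic-data generator

The generator emulates the structure of a three-cohort liver study —
cohort sizes default to 49/96/96, a deceased-donor ChIP cohort plus two
larger expression panels, pooled molecular n = 241 — and is a pure
function of its `sim_config()`: identical configurations give
byte-identical output.

*Genotypes.* LD is a Gaussian copula over blocks of consecutive
variants: per haplotype, an equicorrelated latent vector (shared block
factor, correlation `within_block_corr`, default 0.8) is thresholded at
the variant's target allele frequency; two haplotypes sum to dosages.
Target MAF is drawn once per LD block — variants in strong LD share
allele frequencies, and equal thresholds keep the realized dosage
`r^2` near the latent correlation — uniformly on (0.1, 0.5) by default.
Variants whose realized cohort MAF falls below 5% are redrawn and then
dropped, mirroring the usual post-imputation exclusion.

*Phenotypes.* A configurable fraction of features (default 0.5)
receives one causal variant uniform over its cis window and a
standardized effect (Normal with `effect_size_sd`, or fixed
`effect_size` with random sign). Expression is effect x standardized
dosage + covariate loadings + standard normal noise; peaks are
negative-binomial counts (baseline mean 60, dispersion 0.2) with the
effect on the log mean, so retained peaks satisfy the mean-20 filter by
construction and the dispersion-to-zero limit is Poisson.

*GWAS.* Summary statistics for a locus come either from an explicit
simulated cohort (`method = "cohort"`, the default: genotypes drawn
from the same block copula, marginal regressions computed exactly) or
from the analytic approximation `z ~ MVN(sqrt(n) R lambda, R)` over the
reference LD matrix R (`method = "analytic"`, with a 0.5% diagonal
ridge for positive definiteness). Shared loci reuse the molecular
trait's causal variant; distinct loci draw a causal with reference
`r^2` below 0.5 (0.2 in the recovery studies) to it. Validation runs
that simulate hundreds of 50,000-sample loci use the analytic mode;
the two modes are checked against each other on small cohorts.

*Interactions and annotations.* Peaks sit 25 kb from their
neighbouring gene's TSS so a shared causal variant can fall inside both
the peak's 10 kb window and the gene's 1 Mb window; interaction calls
are emitted at both resolutions with a configurable fraction of
4-fragment calls containing their 1-fragment twin, scores at least 5,
and all pairs within 1 Mb. Per-variant annotation (MAF, gene density,
nearest-gene distance, LD buddies) feeds the matched-null sampler.
M-value profiles are beta-distributed noise around a planted 0/1
sharing indicator whose tissue count encodes the planted class.

*What the generator does not emulate:* real human LD (block-diagonal
equicorrelation only), allele-specific read counts, read-level data,
population structure or relatedness, multiple chromosomes per study
(one synthetic chromosome), and realistic effect-size distributions —
no published estimates exist at matched scale, so planted effects are
a documented free choice. Passing tests therefore demonstrate
correctness of the statistical machinery under the stated generative
model, not robustness to every artifact of real data.

# Validation problem sizes

The acceptance-style checks run at sizes chosen to make their
statistical targets meaningful while keeping a laptop-scale footprint:
null calibration on 500 null genes x 3 cohorts (~50 cis variants per
gene, 500 permutations); false-discovery control over 200 replicate
studies of 100 genes with 10% planted effects at standardized beta 0.6
(realized mean FDP ~0.03 at q = 0.05, power ~0.94); beta-approximation
fidelity on 200 features at 2,000 permutations (rank correlation
>0.999 with the direct empirical p); colocalization recovery over 100
shared and 100 distinct simulated loci (200 variants, GWAS n = 50,000,
molecular n = 241); and co-regulation linking over 30 gene-peak pairs
at n = 241 with unit effects (precision and recall 1.0 at the
`r^2 > 0.8` threshold). `scripts/acceptance.R` recomputes all of these
from a single seed.

# Known limitations

Effect sizes, priors, and the matched-null tolerances interact with
panel size: on small synthetic panels the SNPsnap-style tolerances are
frequently unsatisfiable and the demo pipeline widens them — real
applications should match against genome-scale pools. The empirical
FDR threshold has the granularity of one permutation pass; very small
feature sets make it conservative. The hQTL scan ignores
allele-specific signal and GC-content offsets. Colocalization assumes
a single causal variant per trait per locus, and the greedy 2 Mb locus
definition can split extended signals.
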