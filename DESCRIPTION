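Package: qtlweave
Title: Integrative Molecular QTL Mapping, Meta-Analysis, and GWAS
    Colocalization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for integrative fine-mapping of complex-trait loci with
    molecular quantitative trait data. Implements cis-eQTL and histone-QTL
    scanning with beta-approximated permutation p-values, sample-size
    weighted meta-analysis across cohorts with a permutation-based
    empirical false discovery rate, approximate-Bayes-factor
    colocalization of GWAS and molecular QTL signals, linkage
    disequilibrium based linking of regulatory elements to genes and
    traits, promoter-capture interaction integration at two fragment
    resolutions, and matched-SNP null-set enrichment. A multi-cohort
    synthetic-data generator with planted causal variants supports end to
    end validation of every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    GenomicRanges,
    IRanges,
    limma,
    stats,
    utils
Suggests:
    jsonlite,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
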