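# Internal helpers shared across modules.

#' @importFrom stats cor pt pnorm qnorm pbeta rnorm rbinom rbeta runif sd var
#' @importFrom stats complete.cases fisher.test ks.test optim p.adjust rnbinom
#' @importFrom stats setNames wilcox.test quantile
NULL

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded generators do not
#' perturb the caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Column-standardize a matrix; zero-variance columns come back as NA columns
# so callers can drop monomorphic variants explicitly.
standardize_cols <- function(x) {
  x <- as.matrix(x)
  mu <- colMeans(x)
  xc <- sweep(x, 2, mu, "-")
  s <- sqrt(colSums(xc^2) / (nrow(x) - 1))
  bad <- s < .Machine$double.eps^0.5
  s[bad] <- NA_real_
  sweep(xc, 2, s, "/")
}

# Two-sided p-value for a Pearson correlation at the given residual df.
cor_pvalue <- function(r, df) {
  r <- pmin(pmax(r, -1), 1)
  t <- abs(r) * sqrt(df / pmax(1 - r^2, .Machine$double.xmin))
  p <- 2 * pt(t, df = df, lower.tail = FALSE)
  pmax(p, .Machine$double.xmin)
}

logsumexp <- function(x) {
  x <- x[is.finite(x) | x == -Inf]
  if (!length(x)) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

# log(exp(a) - exp(b)) with a >= b expected; returns -Inf on numerical ties.
logdiffexp <- function(a, b) {
  if (b >= a) return(-Inf)
  a + log1p(-exp(b - a))
}

#' Default MHC exclusion interval
#'
#' The major histocompatibility complex region on chromosome 6 (hg19,
#' 0-based half-open) whose long-range LD makes lead-variant linking
#' unreliable; linking outputs drop signals inside it.
#' @return A list with elements `chrom`, `start`, `end`.
#' @export
mhc_interval <- function() {
  list(chrom = "chr6", start = 28510120L, end = 33480577L)
}

# TRUE for positions falling inside an exclusion interval (half-open).
in_interval <- function(chrom, pos, interval) {
  if (is.null(interval)) return(rep(FALSE, length(pos)))
  chrom == interval$chrom & pos >= interval$start & pos < interval$end
}
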