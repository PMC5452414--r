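#' Two-sided Fisher's exact test for a 2x2 table
#'
#' Exact hypergeometric test with both margins fixed, used to compare pooled
#' methylated/unmethylated counts of a genomic bin between two samples. The
#' two-sided p-value follows the point-probability rule: it is the sum of
#' probabilities of all tables (with the observed margins) whose point
#' probability does not exceed that of the observed table. This matches the
#' convention of `stats::fisher.test` but is implemented directly so that the
#' test and its brute-force oracle remain independent.
#'
#' @param a,b,c,d the four cell counts; rows are samples, columns are
#'   methylated/unmethylated (or any 2x2 layout — the test is symmetric).
#' @return two-sided p-value in (0, 1].
#' @examples
#' fisher_exact_2x2(5, 5, 5, 5)   # 1
#' fisher_exact_2x2(10, 0, 0, 10) # 2/choose(20,10)
#' @export
fisher_exact_2x2 <- function(a, b, c, d) {
  .check_count(c(a, b, c, d), "2x2 table cells")
  if (a + b + c + d == 0)
    .stopf("all-zero 2x2 table: test undefined")
  m <- a + b          # row 1 total
  n <- c + d          # row 2 total
  k <- a + c          # column 1 total
  lo <- max(0, k - n)
  hi <- min(k, m)
  x <- lo:hi
  dens <- stats::dhyper(x, m, n, k)
  p0 <- stats::dhyper(a, m, n, k)
  # tolerance guards against ties lost to floating-point noise
  p <- sum(dens[dens <= p0 * (1 + 1e-7)])
  min(max(p, p0), 1)
}

#' Vectorised Fisher's exact test
#'
#' @param a,b,c,d equal-length integer vectors of cell counts.
#' @return vector of two-sided p-values.
#' @export
fisher_exact_2x2_vec <- function(a, b, c, d) {
  mapply(fisher_exact_2x2, a, b, c, d, USE.NAMES = FALSE)
}

#' Exact conditional binomial test for two count libraries
#'
#' Compares one feature's counts between two libraries of known total size.
#' Under the null hypothesis of equal per-read rates, conditional on the
#' total x1 + x2, x1 is Binomial(x1 + x2, n1 / (n1 + n2)). The two-sided
#' p-value sums the probabilities of all outcomes whose point probability
#' does not exceed that of the observed x1. This is the self-contained
#' stand-in used for differential siRNA-region and expression testing when
#' a single library per genotype is available and dispersion cannot be
#' estimated.
#'
#' @param x1,x2 counts in libraries 1 and 2.
#' @param n1,n2 library sizes (total mapped reads), must be positive.
#' @return two-sided p-value in (0, 1].
#' @examples
#' conditional_binomial_test(0, 10, 1e6, 1e6) # 2/1024
#' @export
conditional_binomial_test <- function(x1, x2, n1, n2) {
  .check_count(c(x1, x2), "counts")
  if (n1 <= 0 || n2 <= 0) .stopf("library sizes must be positive")
  n <- x1 + x2
  if (n == 0) .stopf("x1 + x2 = 0: test undefined (pre-filter such rows)")
  pr <- n1 / (n1 + n2)
  dens <- stats::dbinom(0:n, n, pr)
  p0 <- stats::dbinom(x1, n, pr)
  p <- sum(dens[dens <= p0 * (1 + 1e-7)])
  min(max(p, p0), 1)
}

#' @rdname conditional_binomial_test
#' @export
conditional_binomial_test_vec <- function(x1, x2, n1, n2) {
  mapply(conditional_binomial_test, x1, x2, n1, n2, USE.NAMES = FALSE)
}

#' Benjamini-Hochberg step-up adjustment
#'
#' `q[(i)] = min_{j >= i} p[(j)] * n / j`, capped at 1, returned in the
#' input order. Implemented directly (not via `p.adjust`) so the adjustment
#' and its oracle stay independent in the test-suite.
#'
#' @param p vector of p-values in \[0, 1\].
#' @return vector of q-values, same length and order as `p`.
#' @export
bh_adjust <- function(p) {
  if (length(p) < 1L) .stopf("empty p-value vector")
  if (any(is.na(p)) || any(p < 0) || any(p > 1))
    .stopf("p-values must lie in [0, 1]")
  n <- length(p)
  o <- order(p)
  ps <- p[o]
  qs <- rev(cummin(rev(ps * n / seq_len(n))))
  qs <- pmin(qs, 1)
  out <- numeric(n)
  out[o] <- qs
  out
}
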