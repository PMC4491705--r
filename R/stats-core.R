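## Exact and approximate statistical primitives shared by every stage of the
## pipeline.  All two-sided exact tests use the minimum-likelihood rule: the
## p-value is the sum of point probabilities not exceeding that of the
## observed outcome, with a 1 + 1e-7 relative tolerance on the comparison to
## absorb floating-point rounding (the convention of stats::binom.test and
## stats::fisher.test).

.REL_TOL <- 1 + 1e-7

.new_test <- function(statistic, estimate, p.value, warning = NA_character_) {
  structure(
    list(statistic = statistic, estimate = estimate, p.value = p.value,
         q.value = NA_real_, warning = warning),
    class = "ctrex_test"
  )
}

#' @export
print.ctrex_test <- function(x, ...) {
  cat("ctrex test: statistic =", format(x$statistic),
      " p =", format.pval(x$p.value), "\n")
  if (!is.na(x$warning)) cat("  warning:", x$warning, "\n")
  invisible(x)
}

#' Exact binomial test
#'
#' Exact test of `k` successes in `n` trials against success probability
#' `p0`.  The two-sided p-value follows the minimum-likelihood rule, i.e. it
#' agrees with [stats::binom.test()].
#'
#' @param k Number of successes (0 <= k <= n).
#' @param n Number of trials (> 0).
#' @param p0 Null success probability, strictly between 0 and 1.
#' @param alternative `"two.sided"` (default), `"less"` or `"greater"`.
#' @return A `ctrex_test` list with `statistic` (= k), `estimate` (= k/n)
#'   and `p.value`.
#' @examples
#' binom_exact(7, 8)$p.value  # 18/256
#' @export
binom_exact <- function(k, n, p0 = 0.5,
                        alternative = c("two.sided", "less", "greater")) {
  alternative <- match.arg(alternative)
  if (length(n) != 1L || is.na(n) || n < 1)
    stop("'n' must be a single positive count")
  if (k < 0 || k > n) stop("'k' must lie in [0, n]")
  if (p0 <= 0 || p0 >= 1) stop("'p0' must be strictly inside (0, 1)")
  p <- .binom_p(k, n, p0, alternative)
  .new_test(statistic = k, estimate = k / n, p.value = p)
}

## vectorised two-sided / one-sided exact binomial p-value
.binom_p <- function(k, n, p0 = 0.5, alternative = "two.sided") {
  stopifnot(length(k) == length(n))
  vapply(seq_along(k), function(i) {
    ki <- k[i]; ni <- n[i]
    if (alternative == "less") return(sum(dbinom(0:ki, ni, p0)))
    if (alternative == "greater") return(sum(dbinom(ki:ni, ni, p0)))
    d <- dbinom(0:ni, ni, p0)
    min(1, sum(d[d <= d[ki + 1L] * .REL_TOL]))
  }, numeric(1))
}

#' Fisher's exact test for a 2x2 table
#'
#' Two-sided conditional exact test on the table `rbind(c(a, b), c(c, d))`,
#' summing hypergeometric probabilities of all tables with the same margins
#' that are no more likely than the observed one.  Agrees with
#' [stats::fisher.test()] but is fast enough for genome-scale per-gene loops
#' and exhaustive verification.
#'
#' A degenerate margin (an all-zero row or column) carries no information;
#' the p-value is 1 and the result carries a warning flag.
#'
#' @param a,b,c,d Non-negative cell counts, first row `a, b`, second `c, d`.
#' @return A `ctrex_test` list; `estimate` is the sample odds ratio
#'   (`a*d / (b*c)`, possibly `Inf` or `NaN`).
#' @examples
#' fisher_exact(3, 0, 0, 3)$p.value  # 0.1
#' @export
fisher_exact <- function(a, b, c, d) {
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0))
    stop("all cell counts must be non-negative")
  warn <- NA_character_
  if (min(a + b, c + d, a + c, b + d) == 0) {
    warn <- "degenerate margin; p set to 1"
    p <- 1
  } else {
    p <- .fisher_p(a, b, c, d)
  }
  .new_test(statistic = a, estimate = (a * d) / (b * c), p.value = p,
            warning = warn)
}

## vectorised two-sided Fisher p-value via dhyper; degenerate margins -> 1
.fisher_p <- function(a, b, c, d) {
  vapply(seq_along(a), function(i) {
    r1 <- a[i] + b[i]; r2 <- c[i] + d[i]; m1 <- a[i] + c[i]
    if (min(r1, r2, m1, b[i] + d[i]) == 0) return(1)
    lo <- max(0L, m1 - r2); hi <- min(r1, m1)
    dens <- dhyper(lo:hi, r1, r2, m1)
    min(1, sum(dens[dens <= dhyper(a[i], r1, r2, m1) * .REL_TOL]))
  }, numeric(1))
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment; a thin wrapper around
#' [stats::p.adjust()] that preserves input order and length.
#'
#' @param p Vector of p-values in `[0, 1]` (NA allowed, propagated).
#' @return q-values in the input order, each `>=` its p-value, capped at 1.
#' @export
bh_fdr <- function(p) {
  if (length(p) == 0L) return(numeric(0))
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  p.adjust(p, method = "BH")
}

#' Pooled two-proportion Z-test
#'
#' Compares `k1/n1` with `k2/n2` using the pooled-variance normal
#' approximation without continuity correction:
#' \deqn{Z = |p_1 - p_2| / \sqrt{\hat p (1 - \hat p)(1/n_1 + 1/n_2)}}
#' with \eqn{\hat p = (k_1 + k_2)/(n_1 + n_2)}, and a two-sided normal
#' p-value.  When the pooled proportion is 0 or 1 the statistic is
#' undefined; Z is reported as 0 with p = 1 and a warning flag.
#'
#' @param k1,n1 Successes and trials in the first sample.
#' @param k2,n2 Successes and trials in the second sample.
#' @return A `ctrex_test` list; `statistic` is Z, `estimate` the two
#'   proportions.
#' @examples
#' two_prop_z(1, 30, 20, 87)  # Z = 2.42, p = 0.016
#' @export
two_prop_z <- function(k1, n1, k2, n2) {
  if (n1 < 1 || n2 < 1) stop("both sample sizes must be positive")
  if (k1 < 0 || k1 > n1 || k2 < 0 || k2 > n2)
    stop("counts must lie within their sample sizes")
  p1 <- k1 / n1; p2 <- k2 / n2
  pooled <- (k1 + k2) / (n1 + n2)
  if (pooled == 0 || pooled == 1) {
    return(.new_test(statistic = 0, estimate = c(p1, p2), p.value = 1,
                     warning = "pooled proportion degenerate"))
  }
  z <- abs(p1 - p2) / sqrt(pooled * (1 - pooled) * (1 / n1 + 1 / n2))
  .new_test(statistic = z, estimate = c(p1, p2),
            p.value = 2 * pnorm(-z))
}

#' Pearson correlation with t-based p-value
#'
#' @param x,y Numeric vectors of equal length (>= 3) with non-zero variance.
#' @return A `ctrex_test` list; `estimate` is r, `statistic` the t value.
#' @export
pearson_r <- function(x, y) {
  if (length(x) != length(y)) stop("'x' and 'y' must have equal length")
  if (length(x) < 3) stop("need at least 3 observations")
  if (var(x) == 0 || var(y) == 0)
    stop("correlation undefined: zero variance")
  ct <- cor.test(x, y, method = "pearson")
  .new_test(statistic = unname(ct$statistic), estimate = unname(ct$estimate),
            p.value = ct$p.value)
}

#' Percentage rounded to one decimal
#'
#' Formatting convention used in the reported summaries (e.g. 1/30 -> 3.3,
#' 20/87 -> 23.0).
#'
#' @param k,n Numerator and denominator.
#' @return `round(100 * k / n, 1)`.
#' @export
pct1 <- function(k, n) round(100 * k / n, 1)
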