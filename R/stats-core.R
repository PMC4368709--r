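# Exact and rank statistics shared by all analysis stages. Pure computation;
# no file I/O.

#' Hypergeometric probability mass
#'
#' P(X = k) for the fixed-margin (hypergeometric) distribution with
#' population size `N`, `K` marked items and `n` draws, evaluated in log
#' space via `lchoose` for numerical stability. Values of `k` outside the
#' support return 0.
#'
#' @param k Number of marked items drawn (vectorised).
#' @param N Population size.
#' @param K Number of marked items in the population.
#' @param n Number of draws.
#' @return Numeric vector of probabilities.
#' @export
hypergeom_pmf <- function(k, N, K, n) {
  if (K < 0 || n < 0 || K > N || n > N)
    .data_error("hypergeometric parameters require 0 <= K, n <= N")
  lo <- max(0, n + K - N); hi <- min(n, K)
  p <- rep(0, length(k))
  ok <- k >= lo & k <= hi & k == floor(k)
  p[ok] <- exp(lchoose(K, k[ok]) + lchoose(N - K, n - k[ok]) - lchoose(N, n))
  p
}

#' Fisher's exact test on a 2x2 table
#'
#' Exact test conditioning on both margins. The two-sided p-value sums the
#' hypergeometric probabilities of every table in the support whose
#' probability does not exceed that of the observed table, using a relative
#' tolerance of 1e-7 to absorb floating-point ties (the convention of
#' standard statistical environments). The reported estimate is the
#' unconditional sample odds ratio `(a*d)/(b*c)`; it is `Inf` when
#' `b*c == 0` with `a*d > 0` and `NaN` when both products vanish.
#'
#' @param a,b,c,d Nonnegative integer cell counts. Row 1 = focal group
#'   (`a` in-feature, `b` out-of-feature), row 2 = comparison group. A 2x2
#'   matrix may be supplied as `a` instead.
#' @param sided `"two_sided"` (default) or `"greater"` (upper tail of `a`).
#' @return A list with `p_value`, `estimate` (odds ratio), `direction`
#'   (`"enriched"`, `"depleted"` or `"none"`) and the four counts.
#' @export
fisher_exact <- function(a, b = NULL, c = NULL, d = NULL,
                         sided = c("two_sided", "greater")) {
  sided <- match.arg(sided)
  if (is.matrix(a)) {
    if (!all(dim(a) == c(2, 2))) .data_error("table must be 2x2")
    d <- a[2, 2]; c <- a[2, 1]; b <- a[1, 2]; a <- a[1, 1]
  }
  cells <- c(a, b, c, d)
  if (any(is.na(cells)) || any(cells < 0) || any(cells != floor(cells)))
    .data_error("cell counts must be nonnegative integers")
  if (sum(cells) == 0) .data_error("empty table")
  N <- a + b + c + d
  K <- a + b      # row-1 margin
  n <- a + c      # column-1 margin
  lo <- max(0, n + K - N); hi <- min(n, K)
  ks <- lo:hi
  pmf <- hypergeom_pmf(ks, N, K, n)
  p_obs <- pmf[ks == a]
  p <- if (sided == "greater") sum(pmf[ks >= a]) else
    sum(pmf[pmf <= p_obs * (1 + 1e-7)])
  p <- min(1, p)
  ad <- a * d; bc <- b * c
  est <- if (bc == 0 && ad == 0) NaN else if (bc == 0) Inf else ad / bc
  direction <- if (is.nan(est) || est == 1) "none" else
    if (est > 1) "enriched" else "depleted"
  list(p_value = p, estimate = est, direction = direction,
       a = a, b = b, c = c, d = d)
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up FDR adjustment: with order statistics `p(1) <= ... <= p(m)`, the
#' adjusted value for rank `i` is `min(1, min_{j >= i} m * p(j) / j)`,
#' returned in the input's original order. Thin validated front-end over
#' `stats::p.adjust(method = "BH")`.
#'
#' @param p_values Numeric vector of p-values in `[0, 1]`.
#' @return Numeric vector of adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p_values) {
  if (length(p_values) == 0) return(numeric())
  if (any(is.na(p_values)) || any(p_values < 0) || any(p_values > 1))
    .data_error("p-values must lie in [0, 1]")
  stats::p.adjust(p_values, method = "BH")
}

#' Mann-Whitney U test
#'
#' Two-sided rank-sum comparison of two groups. The exact permutation
#' distribution is used when the pooled sample size is at most 20 and no
#' ties are present; otherwise the normal approximation with tie and
#' continuity corrections is used. The reported estimate is the U statistic
#' for group `x`.
#'
#' @param x,y Numeric vectors (both nonempty).
#' @return A list with `estimate` (U for `x`), `p_value` and `method`.
#' @export
mann_whitney_u <- function(x, y) {
  if (length(x) == 0 || length(y) == 0)
    .data_error("both groups must be nonempty")
  ties <- any(duplicated(c(x, y)))
  exact <- (length(x) + length(y) <= 20) && !ties
  wt <- if (exact)
    stats::wilcox.test(x, y, alternative = "two.sided", exact = TRUE)
  else
    suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                        exact = FALSE, correct = TRUE))
  list(estimate = unname(wt$statistic), p_value = wt$p.value,
       method = if (exact) "exact" else "normal_approximation")
}

#' Fold enrichment
#'
#' Ratio of the hit rate among selected genes to the base rate of the
#' reference set in the background universe:
#' `(hits/selected) / (set_size/background)`.
#'
#' @param hits Selected genes that are also in the reference set.
#' @param selected Size of the selected (candidate) set.
#' @param set_size Size of the reference set.
#' @param background Size of the background universe.
#' @return The fold enrichment; 0 when `hits == 0`, `NaN` when
#'   `set_size == 0`.
#' @export
fold_enrichment <- function(hits, selected, set_size, background) {
  if (selected == 0) .data_error("selected set is empty")
  if (hits < 0 || hits > selected || selected > background ||
      set_size < 0 || set_size > background)
    .data_error("require 0 <= hits <= selected <= background and 0 <= set_size <= background")
  if (set_size == 0) return(NaN)
  (hits / selected) / (set_size / background)
}
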