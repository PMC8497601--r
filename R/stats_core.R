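#' Statistical kernels used across the pipeline
#'
#' Small self-contained wrappers around the tests the comparative analysis
#' relies on: exact hypergeometric tail probabilities, chi-square
#' goodness-of-fit, Kruskal-Wallis with Dunn's post-hoc comparisons,
#' Spearman correlation, and Benjamini-Hochberg adjustment.
#'
#' @name stats_core
NULL

new_test_result <- function(statistic, p_value, method, ...) {
  structure(list(statistic = unname(statistic), p_value = unname(p_value),
                 method = method, ...),
            class = "test_result")
}

#' @export
print.test_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.6g, p = %.4g\n", x$method, x$statistic,
              x$p_value))
  invisible(x)
}

#' Upper-tail hypergeometric probability P(X >= k)
#'
#' Exact tail probability that at least `k` of `n` draws (without
#' replacement) from a universe of `N` items, `K` of which are marked,
#' are marked. Used for the gene-level overlap test between
#' DMR-associated genes and differentially expressed genes.
#'
#' @param N universe size.
#' @param K number of marked items in the universe.
#' @param n number of items drawn.
#' @param k observed number of marked items among the draws.
#' @return Upper-tail probability, a number in \[0, 1\].
#' @examples
#' hypergeom_tail(20, 5, 4, 2)  # 1205/4845
#' @export
hypergeom_tail <- function(N, K, n, k) {
  stopifnot(length(N) == 1, length(K) == 1, length(n) == 1, length(k) == 1)
  if (any(c(N, K, n, k) < 0) || K > N || n > N || k > min(n, K))
    stop("inconsistent hypergeometric arguments: need 0 <= k <= min(n, K) and K, n <= N")
  if (k == 0) return(1)
  # exact sum of point masses over [k, min(n, K)], accumulated in log space
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Chi-square goodness of fit of observed versus expected counts
#'
#' @param observed,expected equal-length numeric vectors; `expected` must be
#'   strictly positive.
#' @return A `test_result` with the X^2 statistic, df = categories - 1 and
#'   the upper-tail p-value.
#' @export
chi2_goodness_of_fit <- function(observed, expected) {
  if (length(observed) != length(expected))
    stop("observed and expected must have the same length")
  if (any(expected <= 0)) stop("expected counts must be strictly positive")
  stat <- sum((observed - expected)^2 / expected)
  df <- length(observed) - 1L
  p <- if (df == 0L) 1 else stats::pchisq(stat, df = df, lower.tail = FALSE)
  new_test_result(stat, p, "chi-square goodness of fit", df = df)
}

#' Kruskal-Wallis omnibus test with Dunn's pairwise comparisons
#'
#' Omnibus tie-corrected Kruskal-Wallis H, followed by Dunn's z tests on
#' mean ranks with tie-corrected variance. Pairwise p-values are two-sided
#' and adjusted across pairs (Benjamini-Hochberg by default).
#'
#' @param groups a named or unnamed list of numeric vectors (>= 2 groups).
#' @param p_adjust_method method passed to [stats::p.adjust()]; `"BH"` by
#'   default, `"bonferroni"` available.
#' @return A list with `omnibus` (a `test_result` carrying H and df) and
#'   `pairwise`, a data.frame with columns group1, group2, z, p_value,
#'   p_adjusted.
#' @export
kruskal_dunn <- function(groups, p_adjust_method = "BH") {
  stopifnot(is.list(groups), length(groups) >= 2)
  if (is.null(names(groups)) || any(names(groups) == ""))
    names(groups) <- paste0("group", seq_along(groups))
  sizes <- lengths(groups)
  if (any(sizes < 1)) stop("every group needs at least one observation")
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), sizes), levels = names(groups))
  N <- length(x)
  if (N < 3) stop("need at least 3 observations in total")

  r <- rank(x)
  tie_tab <- table(x)
  tie_term <- sum(tie_tab^3 - tie_tab)
  mean_rank <- tapply(r, g, mean)

  if (length(unique(x)) == 1L) {
    omnibus <- new_test_result(0, 1, "Kruskal-Wallis rank sum test",
                               df = length(groups) - 1L)
  } else {
    kw <- stats::kruskal.test(x, g)
    omnibus <- new_test_result(kw$statistic, kw$p.value,
                               "Kruskal-Wallis rank sum test",
                               df = unname(kw$parameter))
  }

  # Dunn's pairwise z on mean ranks, tie-corrected pooled variance
  pairs <- utils::combn(names(groups), 2, simplify = FALSE)
  var_core <- N * (N + 1) / 12 - tie_term / (12 * (N - 1))
  pw <- lapply(pairs, function(pr) {
    n1 <- sizes[[pr[1]]]; n2 <- sizes[[pr[2]]]
    se <- sqrt(var_core * (1 / n1 + 1 / n2))
    z <- if (se == 0) 0 else (mean_rank[[pr[1]]] - mean_rank[[pr[2]]]) / se
    data.frame(group1 = pr[1], group2 = pr[2], z = z,
               p_value = 2 * stats::pnorm(-abs(z)))
  })
  pw <- do.call(rbind, pw)
  pw$p_adjusted <- stats::p.adjust(pw$p_value, method = p_adjust_method)
  list(omnibus = omnibus, pairwise = pw)
}

#' Spearman rank correlation with significance test
#'
#' Rho on average ranks (ties averaged); p-value by t-approximation, or the
#' exact permutation distribution for n <= 9.
#'
#' @param x,y paired numeric vectors without missing values, n >= 3.
#' @return A `test_result` with `statistic` = rho, `p_value` and `n`.
#' @export
spearman_rho <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  n <- length(x)
  if (n < 3) stop("need n >= 3")
  if (anyNA(x) || anyNA(y)) stop("missing values not allowed")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("Spearman correlation undefined for a constant vector")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = n <= 9))
  new_test_result(unname(ct$estimate), ct$p.value,
                  "Spearman rank correlation", n = n)
}

#' Benjamini-Hochberg false-discovery-rate adjustment
#'
#' Step-up adjustment (p * m / i with monotonicity enforcement, capped at
#' 1), returned in the original input order.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same length and order as the input.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}
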