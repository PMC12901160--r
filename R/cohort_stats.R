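# Nonparametric cohort statistics: two-sided Mann-Whitney U, Holm-Sidak
# step-down adjustment, Spearman correlation, and median/IQR summaries.
# The tests delegate to the standard routines in stats; enumeration and
# hand-worked oracles live in the test suite.

#' Two-sided Mann-Whitney U test
#'
#' U counts pairs with `x_i > y_j` plus half the ties. The p value is exact
#' (full enumeration over label assignments) whenever the samples are
#' tie-free and `n_x * n_y` does not exceed `exact_limit`; otherwise the
#' normal approximation with tie-corrected variance and continuity correction
#' is used.
#'
#' @param x,y numeric samples (NAs dropped; both must be non-empty).
#' @param exact_limit largest `n_x * n_y` for which the exact null
#'   distribution is enumerated.
#' @return object of class `sscp_test`: `statistic` (U), `p_value`, `method`
#'   (`"exact"` or `"normal_approx"`), `n_x`, `n_y`.
#' @export
mann_whitney <- function(x, y, exact_limit = 10000L) {
  x <- x[!is.na(x)]; y <- y[!is.na(y)]
  if (length(x) == 0L || length(y) == 0L) {
    abort_validation("mann_whitney needs non-empty samples")
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  use_exact <- !ties && length(x) * length(y) <= exact_limit
  ht <- suppressWarnings(
    stats::wilcox.test(x, y, alternative = "two.sided",
                       exact = use_exact, correct = TRUE))
  structure(list(statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 method = if (use_exact) "exact" else "normal_approx",
                 n_x = length(x), n_y = length(y)),
            class = "sscp_test")
}

#' @export
print.sscp_test <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n = %d vs %d), two-sided p = %.4g [%s]\n",
              x$statistic, x$n_x, x$n_y, x$p_value, x$method))
  invisible(x)
}

#' Adjust p values for multiple comparisons
#'
#' `holm_sidak` is the Holm-Sidak step-down: sort ascending and take the
#' running maximum of `1 - (1 - p_(j))^(m - j + 1)`, clipped to 1. The output
#' is elementwise >= the input and monotone in rank; `none` returns the input.
#'
#' @param p numeric vector of p values in \[0, 1\].
#' @param method `"holm_sidak"` (default) or `"none"`.
#' @return adjusted p values in the original order.
#' @export
adjust_pvalues <- function(p, method = c("holm_sidak", "none")) {
  method <- match.arg(method)
  if (any(!is.finite(p) | p < 0 | p > 1)) {
    abort_validation("p values must lie in [0, 1]")
  }
  if (method == "none" || length(p) == 0L) return(p)
  m <- length(p)
  o <- order(p)
  stepwise <- 1 - (1 - p[o])^(m - seq_len(m) + 1)
  adj <- numeric(m)
  adj[o] <- cummax(pmin(stepwise, 1))
  adj
}

#' Spearman rank correlation
#'
#' Tie-aware rho (Pearson correlation of mid-ranks) with a two-sided p value:
#' exact for small tie-free samples, t-approximation otherwise (the standard
#' behaviour of [stats::cor.test()]). A constant input leaves rho undefined
#' and returns `NA` with a warning.
#'
#' @param x,y numeric vectors of equal length, n >= 3 (pairs with NA dropped).
#' @return list with `rho`, `p_value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) abort_validation("x and y must have equal length")
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) abort_validation("spearman_cor needs n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant input: Spearman rho undefined")
    return(list(rho = NA_real_, p_value = NA_real_, n = length(x)))
  }
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
  list(rho = unname(ct$estimate), p_value = ct$p.value, n = length(x))
}

#' Median and interquartile range
#'
#' Quartiles use linear interpolation between order statistics
#' ([stats::quantile()] type 7) by default; the convention is configurable
#' because other software uses different ones.
#'
#' @param values non-empty numeric vector (NAs dropped).
#' @param type quantile algorithm passed to [stats::quantile()].
#' @return list with `median`, `q1`, `q3`, `n`.
#' @export
summarize_median_iqr <- function(values, type = 7) {
  values <- values[!is.na(values)]
  if (length(values) == 0L) abort_validation("empty sample")
  q <- stats::quantile(values, c(0.25, 0.5, 0.75), type = type, names = FALSE)
  list(median = q[2], q1 = q[1], q3 = q[3], n = length(values))
}
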