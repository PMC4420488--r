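#' Fold-deviation summary of normalized/expected ratios
#'
#' Partitions the per-sequence ratios (normalized reads / expected value)
#' into three bands: within 2-fold of expectation (`0.5 <= r <= 2`),
#' severely under-represented (`r < 0.1`, i.e. more than 10-fold under; this
#' includes unobserved sequences at ratio 0), and everything else. Also
#' reports the log10 spread between the highest and lowest positive ratio.
#'
#' @param ratios Numeric vector of ratios (>= 0), or an `lb_normtab` table
#'   (its `ratio` column is used).
#' @return A tibble of class `lb_bias_report` with columns
#'   `pct_within_2fold`, `pct_over_10fold_under`, `pct_other` (summing to
#'   100), `log10_spread` (`NA` with fewer than 2 positive ratios) and
#'   `n_sequences`.
#' @examples
#' fold_deviation_metrics(c(0.4, 1.0, 2.1, 0.6))
#' @export
fold_deviation_metrics <- function(ratios) {
  if (is.data.frame(ratios)) ratios <- ratios$ratio
  if (length(ratios) == 0) abort("no ratios")
  if (any(is.na(ratios) | ratios < 0)) abort("ratios must be >= 0")
  n <- length(ratios)
  within <- sum(ratios >= 0.5 & ratios <= 2)
  under <- sum(ratios < 0.1)
  pos <- ratios[ratios > 0]
  spread <- if (length(pos) >= 2) log10(max(pos) / min(pos)) else NA_real_
  out <- tibble(
    pct_within_2fold = 100 * within / n,
    pct_over_10fold_under = 100 * under / n,
    pct_other = 100 * (n - within - under) / n,
    log10_spread = spread,
    n_sequences = n
  )
  class(out) <- c("lb_bias_report", class(out))
  out
}

#' @export
tidy.lb_bias_report <- function(x, ...) {
  tidyr::pivot_longer(as_tibble(x), dplyr::everything(),
                      names_to = "metric", values_to = "value")
}

#' Compare two ratio distributions (two-tailed Mann-Whitney)
#'
#' Wilcoxon rank-sum test comparing, e.g., the normalized/expected ratios
#' from two adaptor schemes. The exact distribution is used when both
#' groups have at most 8 observations and no ties; otherwise the normal
#' approximation with tie-corrected variance and continuity correction.
#'
#' @param a,b Numeric vectors.
#' @return A tibble with columns `statistic` (the U statistic for `a`),
#'   `p_value`, `method`, `n_a`, `n_b`.
#' @examples
#' compare_distributions(c(1, 2, 3), c(4, 5, 6))
#' @export
compare_distributions <- function(a, b) {
  if (length(a) == 0 || length(b) == 0) abort("both groups must be non-empty")
  exact <- length(a) <= 8 && length(b) <= 8 && !anyDuplicated(c(a, b))
  ht <- suppressWarnings(
    wilcox.test(a, b, alternative = "two.sided", exact = exact,
                correct = !exact)
  )
  tibble(
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    method = if (exact) "exact" else "normal approximation",
    n_a = length(a), n_b = length(b)
  )
}

#' Squared Pearson correlation between replicate measurements
#'
#' @param x,y Numeric vectors of per-sequence normalized reads, matched by
#'   position (use a join on id upstream).
#' @return Pearson R squared.
#' @examples
#' replicate_correlation(c(1, 2, 3), c(1, 2, 2))
#' @export
replicate_correlation <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) abort("need at least 3 paired values")
  if (var(x) == 0 || var(y) == 0) abort("zero variance in one replicate")
  cor(x, y)^2
}

#' Percentage of sequences discrepant 2-fold or more between replicates
#'
#' A pair is discrepant when `max(x, y) / min(x, y) >= 2`. Pairs where both
#' values are 0 carry no information and are excluded; a pair with exactly
#' one zero is infinitely discrepant and counts as such.
#'
#' @inheritParams replicate_correlation
#' @param fold Discrepancy threshold (default 2).
#' @return Percentage (0-100) of informative pairs that are discrepant.
#' @export
replicate_discrepancy <- function(x, y, fold = 2) {
  stopifnot(length(x) == length(y))
  keep <- !(x == 0 & y == 0)
  x <- x[keep]
  y <- y[keep]
  if (length(x) == 0) abort("no informative pairs (all zero in both)")
  disc <- (x == 0 | y == 0) | (pmax(x, y) / pmin(x, y) >= fold)
  100 * sum(disc) / length(disc)
}
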