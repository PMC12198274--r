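#' Continuity-corrected chi-squared test for a 2x2 table
#'
#' Pearson chi-squared on a 2x2 contingency table (rows = groups, columns =
#' trait present/absent). With `correction = TRUE` (the default) each
#' observed count is moved toward its expected value by
#' `min(0.5, |O - E|)` before summing `(O - E)^2 / E` (Yates correction,
#' clamped so the adjusted deviation is never negative); the p-value is the
#' upper tail of chi-squared with 1 degree of freedom.
#'
#' @param table 2x2 numeric matrix of nonnegative counts.
#' @param correction Apply the continuity correction.
#' @return Tibble with `statistic`, `df`, `p_value`.
#' @export
#' @examples
#' chi2_2x2(matrix(c(245, 199, 136, 282), 2, byrow = TRUE)) # 43.8
chi2_2x2 <- function(table, correction = TRUE) {
  table <- as.matrix(table)
  stopifnot(all(dim(table) == c(2, 2)), all(table >= 0))
  if (sum(table) < 1) abort("grand total must be >= 1.")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    abort("zero row or column margin; expected counts undefined.")
  }
  res <- suppressWarnings(chisq.test(table, correct = correction))
  tibble(statistic = unname(res$statistic), df = 1L,
         p_value = unname(res$p.value))
}

#' Two-sample t-test (pooled or Welch)
#'
#' @param x,y Numeric samples with at least 2 observations each.
#' @param variant `"pooled"` (equal variances, df = n1 + n2 - 2) or
#'   `"welch"` (Welch-Satterthwaite df).
#' @return Tibble with `statistic`, `df`, `p_value`, `variant`.
#' @export
two_sample_t <- function(x, y, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  stopifnot(length(x) >= 2, length(y) >= 2)
  if (var(x) == 0 && var(y) == 0) abort("zero variance in both samples.")
  res <- t.test(x, y, var.equal = variant == "pooled")
  tibble(statistic = unname(res$statistic), df = unname(res$parameter),
         p_value = unname(res$p.value), variant = variant)
}

#' Mann-Whitney test (W statistic)
#'
#' `W` counts the pairs with `x_i > y_j`, ties counted one half
#' (first-sample orientation: all `x` below all `y` gives `W = 0`, all above
#' gives `n1 * n2`). The p-value uses the normal approximation with tie
#' correction.
#'
#' @param x,y Numeric samples.
#' @return Tibble with `statistic` (W) and `p_value`.
#' @export
mann_whitney_w <- function(x, y) {
  stopifnot(length(x) >= 1, length(y) >= 1)
  res <- suppressWarnings(wilcox.test(x, y, exact = FALSE, correct = FALSE))
  tibble(statistic = unname(res$statistic), p_value = unname(res$p.value))
}

#' Descriptive group comparison table
#'
#' Pairwise comparison of two groups over declared variables: continuous
#' variables by two-sample t-test (mean +- SD summaries), binary variables
#' by continuity-corrected chi-squared on the 2x2 count table, and ordinal
#' variables by Mann-Whitney (median and IQR summaries, linear-interpolation
#' quantiles).
#'
#' @param data Data frame with a group column.
#' @param group_col Name of the group column.
#' @param groups Length-2 character vector: the two groups to compare (in
#'   first-sample, second-sample order).
#' @param continuous,binary,ordinal Character vectors of column names by
#'   variable type; binary columns must be coded 0/1.
#' @param t_variant Passed to [two_sample_t()].
#' @return Tibble with one row per variable: summaries per group, `test`,
#'   `statistic`, `df`, `p_value`.
#' @export
cohort_table <- function(data, group_col = "group", groups,
                         continuous = character(), binary = character(),
                         ordinal = character(), t_variant = "pooled") {
  stopifnot(length(groups) == 2)
  g <- as.character(data[[group_col]])
  d1 <- data[g == groups[1], , drop = FALSE]
  d2 <- data[g == groups[2], , drop = FALSE]
  if (!nrow(d1) || !nrow(d2)) abort("empty comparison group.")
  rows <- list()

  fmt_mean <- function(v) sprintf("%.1f ± %.1f", mean(v, na.rm = TRUE),
                                  sd(v, na.rm = TRUE))
  fmt_med <- function(v) {
    q <- quantile(v, c(0.25, 0.5, 0.75), na.rm = TRUE, type = 7)
    sprintf("%g (%g-%g)", q[2], q[1], q[3])
  }
  fmt_n <- function(v) {
    v <- v[!is.na(v)]
    sprintf("%d (%.1f%%)", sum(v == 1), 100 * mean(v == 1))
  }

  for (v in continuous) {
    x <- d1[[v]][!is.na(d1[[v]])]; y <- d2[[v]][!is.na(d2[[v]])]
    tt <- two_sample_t(x, y, t_variant)
    rows[[length(rows) + 1]] <- tibble(
      variable = v, summary_1 = fmt_mean(x), summary_2 = fmt_mean(y),
      test = paste0("t (", t_variant, ")"), statistic = tt$statistic,
      df = tt$df, p_value = tt$p_value
    )
  }
  for (v in binary) {
    x <- d1[[v]]; y <- d2[[v]]
    tab <- rbind(c(sum(x == 1, na.rm = TRUE), sum(x == 0, na.rm = TRUE)),
                 c(sum(y == 1, na.rm = TRUE), sum(y == 0, na.rm = TRUE)))
    ct <- chi2_2x2(tab)
    rows[[length(rows) + 1]] <- tibble(
      variable = v, summary_1 = fmt_n(x), summary_2 = fmt_n(y),
      test = "chi-squared (corrected)", statistic = ct$statistic,
      df = 1, p_value = ct$p_value
    )
  }
  for (v in ordinal) {
    x <- d1[[v]][!is.na(d1[[v]])]; y <- d2[[v]][!is.na(d2[[v]])]
    mw <- mann_whitney_w(x, y)
    rows[[length(rows) + 1]] <- tibble(
      variable = v, summary_1 = fmt_med(x), summary_2 = fmt_med(y),
      test = "Mann-Whitney", statistic = mw$statistic,
      df = NA_real_, p_value = mw$p_value
    )
  }
  out <- dplyr::bind_rows(rows)
  attr(out, "groups") <- groups
  out
}
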