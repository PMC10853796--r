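# Classical tests used across the pipeline, with a uniform one-row tibble
# result (broom-style). The heavy lifting is delegated to the standard
# stats-package implementations; tests in this package check them against
# independent closed-form/enumeration oracles.

test_result <- function(method, statistic, p_value, df = NA_real_,
                        df2 = NA_real_, n = NA_integer_, sidedness = "two") {
  tibble::tibble(method = method, statistic = as.numeric(statistic),
                 p_value = as.numeric(p_value), df = as.numeric(df),
                 df2 = as.numeric(df2), n = as.integer(n),
                 sidedness = sidedness)
}

check_groups <- function(y, g, min_per_group = 1L, min_groups = 2L) {
  keep <- !is.na(y) & !is.na(g)
  y <- y[keep]; g <- as.character(g[keep])
  counts <- table(g)
  if (length(counts) < min_groups) {
    abort(sprintf("need at least %d groups", min_groups),
          class = "metalsplice_value_error")
  }
  if (any(counts < min_per_group)) {
    abort(sprintf("group(s) with fewer than %d observations: %s",
                  min_per_group,
                  paste(names(counts)[counts < min_per_group],
                        collapse = ", ")),
          class = "metalsplice_value_error")
  }
  list(y = y, g = factor(g))
}

#' One-way analysis of variance
#'
#' Classical single-factor ANOVA on a long data frame.
#'
#' @param data Data frame with one observation per row.
#' @param value,group Unquoted column names of the response and the group
#'   label.
#' @return One-row tibble: `method`, `statistic` (F), `p_value`, `df`
#'   (between), `df2` (within), `n`, `sidedness`.
#' @export
one_way_anova <- function(data, value, group) {
  y <- dplyr::pull(data, {{ value }})
  g <- dplyr::pull(data, {{ group }})
  gd <- check_groups(y, g, min_per_group = 2L)
  tab <- stats::anova(stats::aov(gd$y ~ gd$g))
  f <- tab$`F value`[1L]
  p <- tab$`Pr(>F)`[1L]
  # all observations identical: SSW = SSB = 0 -> define F = 0, p = 1
  if (!is.finite(f) && stats::var(gd$y) == 0) { f <- 0; p <- 1 }
  test_result("one-way ANOVA", f, p, df = tab$Df[1L], df2 = tab$Df[2L],
              n = length(gd$y))
}

#' Tukey-Kramer post-hoc contrasts
#'
#' All pairwise group contrasts after a one-way ANOVA, using studentized-
#' range quantiles with the unequal-n (Kramer) correction.
#'
#' @inheritParams one_way_anova
#' @param conf_level Confidence level for the intervals.
#' @return Tibble: `contrast`, `diff`, `conf_low`, `conf_high`, `p_adj`.
#' @export
tukey_kramer <- function(data, value, group, conf_level = 0.95) {
  y <- dplyr::pull(data, {{ value }})
  g <- dplyr::pull(data, {{ group }})
  gd <- check_groups(y, g, min_per_group = 2L)
  hsd <- stats::TukeyHSD(stats::aov(gd$y ~ gd$g),
                         conf.level = conf_level)[["gd$g"]]
  tibble::tibble(contrast = rownames(hsd), diff = hsd[, "diff"],
                 conf_low = hsd[, "lwr"], conf_high = hsd[, "upr"],
                 p_adj = hsd[, "p adj"])
}

#' Kruskal-Wallis rank test
#'
#' Non-parametric one-way analysis with tie correction; p-value from the
#' chi-square approximation.
#'
#' @inheritParams one_way_anova
#' @return One-row tibble with H as `statistic`.
#' @export
kruskal_wallis <- function(data, value, group) {
  y <- dplyr::pull(data, {{ value }})
  g <- dplyr::pull(data, {{ group }})
  gd <- check_groups(y, g)
  if (stats::var(gd$y) == 0) {
    return(test_result("Kruskal-Wallis", 0, 1,
                       df = length(levels(gd$g)) - 1L, n = length(gd$y)))
  }
  kt <- stats::kruskal.test(gd$y, gd$g)
  test_result("Kruskal-Wallis", kt$statistic, kt$p.value,
              df = kt$parameter, n = length(gd$y))
}

#' Mann-Whitney U test
#'
#' Rank-sum comparison of two samples. Uses the exact null distribution
#' when both samples have at most 8 observations and there are no ties;
#' otherwise the normal approximation with tie correction (no continuity
#' correction). The statistic is U for the first sample.
#'
#' @param a,b Numeric vectors.
#' @param alternative `"two.sided"`, `"less"` or `"greater"`.
#' @return One-row tibble.
#' @export
mann_whitney_u <- function(a, b, alternative = "two.sided") {
  alternative <- match.arg(alternative, c("two.sided", "less", "greater"))
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) {
    abort("both samples must be non-empty",
          class = "metalsplice_value_error")
  }
  side <- if (alternative == "two.sided") "two" else "one"
  if (stats::var(c(a, b)) == 0) {
    u <- length(a) * length(b) / 2
    return(test_result("Mann-Whitney U", u, 1, n = length(a) + length(b),
                       sidedness = side))
  }
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- length(a) <= 8L && length(b) <= 8L && !ties
  wt <- suppressWarnings(
    stats::wilcox.test(a, b, alternative = alternative, exact = exact,
                       correct = FALSE))
  test_result(paste0("Mann-Whitney U (",
                     if (exact) "exact" else "normal approx", ")"),
              wt$statistic, wt$p.value, n = length(a) + length(b),
              sidedness = side)
}

#' Mood's median test
#'
#' Dichotomizes both samples at the pooled median (values above versus not
#' above) and applies a 2x2 chi-square test without continuity correction.
#'
#' @param a,b Numeric vectors.
#' @return One-row tibble.
#' @export
median_test <- function(a, b) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) {
    abort("both samples must be non-empty",
          class = "metalsplice_value_error")
  }
  m <- stats::median(c(a, b))
  tab <- rbind(c(sum(a > m), sum(a <= m)),
               c(sum(b > m), sum(b <= m)))
  if (any(colSums(tab) == 0L)) {
    return(test_result("median test", 0, 1, df = 1,
                       n = length(a) + length(b)))
  }
  ct <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))
  test_result("median test", ct$statistic, ct$p.value, df = 1,
              n = length(a) + length(b))
}

#' Pearson chi-square test on an r x c contingency table
#'
#' @param table Matrix of non-negative counts; no all-zero row or column.
#' @param correct Apply the Yates continuity correction (2x2 only);
#'   default FALSE.
#' @return One-row tibble with df = (r-1)(c-1).
#' @export
chi2_contingency <- function(table, correct = FALSE) {
  table <- as.matrix(table)
  if (any(table < 0) || anyNA(table)) {
    abort("counts must be non-negative", class = "metalsplice_value_error")
  }
  if (any(rowSums(table) == 0) || any(colSums(table) == 0) ||
      nrow(table) < 2L || ncol(table) < 2L) {
    abort("degenerate table: need >= 2 rows and columns, none all-zero",
          class = "metalsplice_value_error")
  }
  ct <- suppressWarnings(stats::chisq.test(table, correct = correct))
  test_result("Pearson chi-square", ct$statistic, ct$p.value,
              df = ct$parameter, n = sum(table))
}

#' Exact binomial test
#'
#' Exact tail probabilities of the binomial distribution; the two-sided
#' p-value sums all outcomes with point probability at most that of the
#' observed count. Directional claims in this package use the one-sided
#' test, which is the default.
#'
#' @param k Observed successes.
#' @param n Number of trials.
#' @param p0 Null success probability.
#' @param alternative `"greater"` (default), `"less"` or `"two.sided"`.
#' @return One-row tibble with `statistic = k`.
#' @export
binom_exact <- function(k, n, p0 = 0.5, alternative = "greater") {
  alternative <- match.arg(alternative, c("greater", "less", "two.sided"))
  if (k < 0 || k > n) abort("need 0 <= k <= n",
                            class = "metalsplice_value_error")
  if (p0 <= 0 || p0 >= 1) abort("need 0 < p0 < 1",
                                class = "metalsplice_value_error")
  bt <- stats::binom.test(k, n, p = p0, alternative = alternative)
  test_result(paste0("exact binomial (", alternative, ")"), k, bt$p.value,
              n = n, sidedness = if (alternative == "two.sided") "two"
              else "one")
}
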