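#' Choose the two-group test for a variable
#'
#' Assumption-gated test selection: Shapiro-Wilk normality per group at
#' alpha = 0.05 (any failure selects the Mann-Whitney U test); otherwise
#' Levene's test of variance homogeneity at alpha = 0.05 decides between the
#' pooled-variance and Welch t-tests.
#'
#' @param x,y Numeric samples of the two groups, each n >= 3.
#' @param alpha Gate level for both assumption tests.
#' @return List with `test` (`"t_pooled"`, `"t_welch"` or `"mann_whitney"`),
#'   `shapiro_p` (per group) and `levene_p` (NA when normality failed).
#' @export
choose_test <- function(x, y, alpha = 0.05) {
  x <- x[is.finite(x)]; y <- y[is.finite(y)]
  if (length(x) < 3 || length(y) < 3) {
    abort("Need >= 3 values per group.")
  }
  sw <- c(shapiro.test(x)$p.value, shapiro.test(y)$p.value)
  if (any(sw < alpha)) {
    return(list(test = "mann_whitney", shapiro_p = sw, levene_p = NA_real_))
  }
  g <- factor(rep(c("x", "y"), c(length(x), length(y))))
  lev <- car::leveneTest(c(x, y) ~ g)[1, "Pr(>F)"]
  list(test = if (lev < alpha) "t_welch" else "t_pooled",
       shapiro_p = sw, levene_p = lev)
}

#' Percent difference of a group mean from the reference mean
#'
#' `(mean_ref - mean_other) / mean_ref * 100`: how much lower (positive) or
#' higher (negative) the other group's mean is than the reference (control)
#' group's mean.
#'
#' @param mean_ref Reference-group mean, non-zero.
#' @param mean_other Other-group mean.
#' @return Percent difference.
#' @examples
#' percent_difference(0.48, 0.38)  # ~20.8, reported as "21% lower"
#' @export
percent_difference <- function(mean_ref, mean_other) {
  if (any(mean_ref == 0)) abort("`mean_ref` must be non-zero.")
  (mean_ref - mean_other) / mean_ref * 100
}

#' Compare one variable between the two groups
#'
#' Runs the assumption-gated two-sided test selected by [choose_test()] and
#' assembles a tidy comparison row with group descriptives, the percent
#' difference of the first (non-reference) group from the reference group,
#' and a Bonferroni-adjusted P-value (`p_adjusted = min(1, m * p_raw)`;
#' `adjust_m = 2` covers the type I/type II fiber pair, 1 otherwise).
#'
#' @param data Tibble with the variable and a two-level group column.
#' @param variable Name of the numeric column to compare (string).
#' @param group Name of the group column.
#' @param ref Reference (control) group level; defaults to the last level.
#' @param adjust_m Bonferroni multiplicity.
#' @param alpha Gate level passed to [choose_test()].
#' @return One-row tibble of class `group_comparison` fields: `variable`,
#'   `test_used`, `statistic`, `p_raw`, `p_adjusted`, per-group mean/sd,
#'   `percent_difference`.
#' @export
compare_groups <- function(data, variable, group = "group", ref = NULL,
                           adjust_m = 1, alpha = 0.05) {
  stopifnot(is.data.frame(data))
  if (!variable %in% names(data)) abort(paste("No column", variable))
  g <- factor(data[[group]])
  if (nlevels(g) != 2) abort("`group` must have exactly two levels.")
  ref <- ref %||% levels(g)[2]
  if (!ref %in% levels(g)) abort("`ref` is not a group level.")
  other <- setdiff(levels(g), ref)
  v <- data[[variable]]
  x <- v[g == other & is.finite(v)]
  y <- v[g == ref & is.finite(v)]
  sel <- choose_test(x, y, alpha = alpha)
  res <- switch(sel$test,
    t_pooled = t.test(x, y, var.equal = TRUE),
    t_welch = t.test(x, y, var.equal = FALSE),
    mann_whitney = wilcox.test(x, y, exact = FALSE)
  )
  out <- tibble(
    variable = variable,
    test_used = sel$test,
    statistic = unname(res$statistic),
    p_raw = res$p.value,
    p_adjusted = min(1, adjust_m * res$p.value),
    mean_1 = mean(x), sd_1 = sd(x), n_1 = length(x), group_1 = other,
    mean_ref = mean(y), sd_ref = sd(y), n_ref = length(y), group_ref = ref,
    percent_difference = percent_difference(mean(y), mean(x))
  )
  class(out) <- c("group_comparison", class(out))
  out
}

#' Pooled Spearman correlation of Mb concentration and mRNA expression
#'
#' Spearman rank correlation over all subjects pooled into one group, with
#' the explained variance reported as `rho^2 * 100` percent.
#'
#' @param mb Weighted Mb concentrations (mM).
#' @param mrna Relative mRNA expression values, paired with `mb`.
#' @return One-row tibble: `rho`, `p_value`, `explained_variance_pct`, `n`.
#' @export
pooled_spearman <- function(mb, mrna) {
  keep <- is.finite(mb) & is.finite(mrna)
  mb <- mb[keep]; mrna <- mrna[keep]
  if (length(mb) < 4) abort("Need >= 4 paired values.")
  if (sd(mb) == 0 || sd(mrna) == 0) abort("Constant input.")
  ct <- suppressWarnings(cor.test(mb, mrna, method = "spearman"))
  tibble(rho = unname(ct$estimate), p_value = ct$p.value,
         explained_variance_pct = unname(ct$estimate)^2 * 100,
         n = length(mb))
}
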