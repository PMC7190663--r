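# The statistics battery used across the analyses: thin, contract-stable
# wrappers over base R's implementations, with the exact/approximate
# switches pinned down so results are reproducible.

stat_result <- function(statistic, p_value, df_or_n, method, extra = list()) {
  structure(c(list(statistic = statistic, p_value = p_value,
                   df_or_n = df_or_n, method = method), extra),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g (df/n = %.4g)\n",
              x$method, x$statistic, x$p_value, x$df_or_n))
  invisible(x)
}

#' Spearman rank correlation test
#'
#' rho on average-ranked data; the p-value is exact (full permutation
#' null) for n <= 8 with no ties, and the t approximation otherwise.
#'
#' @param x,y numeric vectors of equal length n >= 3.
#' @return A `stat_result` with `statistic` = rho; `estimate` duplicates
#'   rho for convenience.
#' @export
spearman_test <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3L) stop("need equal lengths n >= 3")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("rho undefined for a constant vector")
  ties <- anyDuplicated(x) > 0L || anyDuplicated(y) > 0L
  exact <- n <= 8L && !ties
  ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman",
                                         exact = exact))
  rho <- unname(ct$estimate)
  stat_result(rho, ct$p.value, n,
              if (exact) "spearman (exact)" else "spearman (t approx.)",
              extra = list(estimate = rho))
}

#' One-sided Wilcoxon rank-sum test
#'
#' `alternative = "greater"` tests whether `a` tends larger than `b`.
#' Exact null distribution when the combined sample size is at most 12 and
#' there are no ties; normal approximation with continuity and tie
#' correction otherwise.
#'
#' @param a,b numeric samples (non-empty).
#' @param alternative `"greater"` or `"less"` (direction of `a` vs `b`).
#' @return A `stat_result` with `statistic` = the Mann-Whitney U of `a`.
#' @examples
#' rank_sum_one_sided(c(4, 5, 6), c(1, 2, 3))$p_value # 1/20
#' @export
rank_sum_one_sided <- function(a, b, alternative = c("greater", "less")) {
  alternative <- match.arg(alternative)
  if (length(a) == 0L || length(b) == 0L) stop("both samples must be non-empty")
  ties <- anyDuplicated(c(a, b)) > 0L
  exact <- (length(a) + length(b)) <= 12L && !ties
  wt <- suppressWarnings(stats::wilcox.test(
    a, b, alternative = alternative, exact = exact, correct = TRUE))
  stat_result(unname(wt$statistic), wt$p.value, length(a) + length(b),
              if (exact) "rank-sum (exact)" else "rank-sum (normal approx.)",
              extra = list(alternative = alternative))
}

#' Two-sided t-test
#'
#' Classical t statistic; Welch degrees of freedom when unpaired, n - 1 on
#' the differences when paired.
#'
#' @param a,b numeric samples; equal lengths >= 2 required when paired.
#' @param paired paired test on the differences.
#' @return A `stat_result` with `statistic` = t and `df_or_n` = the
#'   degrees of freedom.
#' @export
t_test_two_sided <- function(a, b, paired = FALSE) {
  if (paired && length(a) != length(b))
    stop("paired test needs equal lengths")
  if (paired && stats::var(a - b) == 0) {
    if (mean(a - b) == 0) # identical pairs: no effect by definition
      return(stat_result(0, 1, length(a) - 1L, "t-test (paired)"))
    stop("zero variance in the paired differences")
  }
  if (!paired && stats::var(a) == 0 && stats::var(b) == 0)
    stop("zero variance in both samples")
  tt <- stats::t.test(a, b, paired = paired)
  stat_result(unname(tt$statistic), tt$p.value, unname(tt$parameter),
              if (paired) "t-test (paired)" else "t-test (Welch)")
}

#' Two-factor ANOVA with interaction (sequential sums of squares)
#'
#' Fits `P ~ M * C` with type-I (sequential) sums of squares, the default
#' of base R's `aov`: the model used to test whether the mitotype donor
#' (M, binary) predicts nuclear genome retention (P, percent) across
#' strain classes (C).
#'
#' @param table data.frame with columns `P` (numeric response), `M` and
#'   `C` (factors or coercible).
#' @return A data.frame with one row per term (`M`, `C`, `M:C`): `df`,
#'   `sum_sq`, `f_value`, `p_value`.
#' @export
anova_two_factor <- function(table) {
  need <- c("P", "M", "C")
  if (!all(need %in% names(table)))
    stop("table needs columns P, M, C")
  d <- data.frame(P = as.numeric(table$P), M = factor(table$M),
                  C = factor(table$C))
  if (nlevels(d$M) < 2L || nlevels(d$C) < 2L)
    stop("each factor needs at least 2 levels")
  if (stats::var(d$P) == 0) {
    # constant response: every term explains nothing
    dfs <- c(nlevels(d$M) - 1L, nlevels(d$C) - 1L,
             (nlevels(d$M) - 1L) * (nlevels(d$C) - 1L))
    return(data.frame(term = c("M", "C", "M:C"), df = dfs, sum_sq = 0,
                      f_value = 0, p_value = 1, stringsAsFactors = FALSE))
  }
  fit <- stats::aov(P ~ M * C, data = d)
  tab <- summary(fit)[[1L]]
  terms <- trimws(rownames(tab))
  resid_df <- tab[terms == "Residuals", "Df"]
  if (length(resid_df) == 0L || resid_df < 1L)
    stop("confounded design: no residual degrees of freedom")
  keep <- terms != "Residuals"
  if (any(tab[keep, "Df"] == 0))
    stop("confounded design: a term has 0 df")
  f <- tab[keep, "F value"]
  p <- tab[keep, "Pr(>F)"]
  # a response with zero variance has 0/0 F ratios: no evidence, F = 0
  zero <- is.nan(f) & tab[keep, "Sum Sq"] == 0
  f[zero] <- 0
  p[zero] <- 1
  data.frame(term = terms[keep], df = tab[keep, "Df"],
             sum_sq = tab[keep, "Sum Sq"], f_value = f, p_value = p,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Simple linear regression with r-squared
#'
#' Ordinary least squares of y on x, reporting slope, intercept, r^2 and
#' the overall F-test p-value.
#'
#' @param x,y numeric vectors, n >= 3; x must not be constant.
#' @return A `stat_result` with `statistic` = slope and extras
#'   `intercept`, `r_squared`.
#' @export
linear_regression <- function(x, y) {
  n <- length(x)
  if (length(y) != n || n < 3L) stop("need equal lengths n >= 3")
  if (stats::var(x) == 0) stop("constant x")
  fit <- stats::lm(y ~ x)
  sm <- suppressWarnings(summary(fit)) # exact fits warn harmlessly
  fs <- sm$fstatistic
  p <- if (is.null(fs)) NA_real_ else
    unname(stats::pf(fs[1L], fs[2L], fs[3L], lower.tail = FALSE))
  stat_result(unname(stats::coef(fit)[2L]), p, n, "linear regression",
              extra = list(intercept = unname(stats::coef(fit)[1L]),
                           r_squared = sm$r.squared))
}
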