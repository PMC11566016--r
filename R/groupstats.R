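# Group-level inference: planned contrasts with pooled variance, directional
# one-sample tests, assumption-dispatched two-group comparisons, Bonferroni
# families, and simple Pearson correlations.

#' Effect-size conventions for reported t statistics
#'
#' \code{cohen_d_contrast} converts a pooled-variance contrast t to Cohen's
#' d via d = 2 t / sqrt(df); \code{cohen_d_one_sample} converts a one-sample
#' t via d = t / sqrt(n).
#'
#' @param t t statistic.
#' @param df Contrast error degrees of freedom (N - k).
#' @param n One-sample size.
#' @return Cohen's d.
#' @export
cohen_d_contrast <- function(t, df) 2 * t / sqrt(df)

#' @rdname cohen_d_contrast
#' @export
cohen_d_one_sample <- function(t, n) t / sqrt(n)

#' Planned one-way contrast with pooled within-group variance
#'
#' Estimate = sum of weights times group means; the standard error uses the
#' pooled mean squared error from all groups' within-group variances with
#' error df = N - k, so every group contributes to the error term even when
#' its weight is zero.
#'
#' @param values_by_group Named list of numeric vectors, one per group.
#' @param weights Named numeric contrast weights covering every group.
#' @return List of class \code{remdiff_contrast}: estimate, se, t, df,
#'   p (two-tailed), d (= 2 t / sqrt(df)).
#' @export
planned_contrast <- function(values_by_group, weights) {
  if (length(values_by_group) < 2L) stop("need >= 2 groups")
  if (!all(names(values_by_group) %in% names(weights)))
    stop("weights must cover all groups")
  ns <- lengths(values_by_group)
  if (any(ns < 2L)) stop("each group needs n >= 2")
  w <- weights[names(values_by_group)]
  means <- vapply(values_by_group, mean, numeric(1))
  vars <- vapply(values_by_group, var, numeric(1))
  N <- sum(ns)
  k <- length(values_by_group)
  df <- N - k
  mse <- sum((ns - 1) * vars) / df
  if (mse <= 0) stop("zero pooled within-group variance")
  estimate <- sum(w * means)
  se <- sqrt(mse * sum(w^2 / ns))
  t <- estimate / se
  structure(list(estimate = estimate, se = se, t = t, df = df,
                 p = 2 * pt(-abs(t), df), d = cohen_d_contrast(t, df),
                 weights = w),
            class = "remdiff_contrast")
}

#' One-sample t test with directional tails and Cohen's d
#'
#' @param values Numeric vector (n >= 2, finite).
#' @param mu Null value (default 0).
#' @param tail \code{"two"}, \code{"less"} or \code{"greater"}.
#' @return List of class \code{remdiff_test}: method, statistic, df, p,
#'   tail, d (= t / sqrt(n)).
#' @export
one_sample_test <- function(values, mu = 0, tail = c("two", "less", "greater")) {
  tail <- match.arg(tail)
  if (length(values) < 2L || any(!is.finite(values)))
    stop("need >= 2 finite values")
  if (sd(values) == 0) stop("zero variance in values")
  n <- length(values)
  t <- (mean(values) - mu) / (sd(values) / sqrt(n))
  df <- n - 1
  p <- switch(tail, two = 2 * pt(-abs(t), df), less = pt(t, df),
              greater = pt(t, df, lower.tail = FALSE))
  structure(list(method = "one_sample_t", statistic = t, df = df, p = p,
                 tail = tail, d = cohen_d_one_sample(t, n)),
            class = "remdiff_test")
}

#' Two-group comparison with assumption-based test dispatch
#'
#' Normality is checked per group (Shapiro-Wilk at \code{alpha_check}); if
#' either group fails, a Wilcoxon rank sum test is reported. Otherwise
#' homogeneity of variances is checked (Levene's test, median-centered); if
#' violated, Welch's t test is reported, else Student's t test. The result
#' records which branch fired.
#'
#' @param a,b Numeric vectors (each n >= 3).
#' @param alpha_check Alpha for the assumption checks (default 0.05).
#' @return List of class \code{remdiff_test}: method (one of
#'   "wilcoxon_rank_sum", "welch_t", "student_t"), statistic, df (t methods),
#'   p (two-tailed), d (t methods, = 2 t / sqrt(df)), checks.
#' @export
two_group_compare <- function(a, b, alpha_check = 0.05) {
  if (length(a) < 3L || length(b) < 3L) stop("each group needs n >= 3")
  if (length(unique(c(a, b))) == 1L)
    stop("all values tied; no test is defined")
  # a constant group cannot be normal; send it to the rank-sum branch
  sw_p <- function(x) if (sd(x) == 0) 0 else shapiro.test(x)$p.value
  sw_a <- sw_p(a)
  sw_b <- sw_p(b)
  checks <- list(shapiro_a = sw_a, shapiro_b = sw_b, levene = NA_real_)
  if (sw_a < alpha_check || sw_b < alpha_check) {
    if (length(unique(c(a, b))) == 1L) stop("all values tied; rank test undefined")
    wt <- suppressWarnings(wilcox.test(a, b))
    out <- list(method = "wilcoxon_rank_sum", statistic = unname(wt$statistic),
                df = NA_real_, p = wt$p.value, d = NA_real_, checks = checks)
  } else {
    lev <- car::leveneTest(c(a, b),
                           factor(rep(c("a", "b"), c(length(a), length(b)))),
                           center = median)
    checks$levene <- lev[["Pr(>F)"]][1L]
    tt <- t.test(a, b, var.equal = checks$levene >= alpha_check)
    method <- if (checks$levene < alpha_check) "welch_t" else "student_t"
    out <- list(method = method, statistic = unname(tt$statistic),
                df = unname(tt$parameter), p = tt$p.value,
                d = cohen_d_contrast(unname(tt$statistic),
                                     unname(tt$parameter)),
                checks = checks)
  }
  structure(out, class = "remdiff_test")
}

#' Bonferroni-adjusted alpha for a family of tests
#'
#' @param family_alpha Family-wise alpha (e.g. 0.05).
#' @param k Number of tests in the family (>= 1).
#' @return List of class \code{remdiff_family}: family_alpha, k,
#'   adjusted_alpha = family_alpha / k.
#' @export
bonferroni_alpha <- function(family_alpha, k) {
  if (k < 1L) stop("k must be >= 1")
  structure(list(family_alpha = family_alpha, k = as.integer(k),
                 adjusted_alpha = family_alpha / k),
            class = "remdiff_family")
}

#' Pearson correlation with a two-tailed p value
#'
#' @param x,y Numeric vectors (n >= 3, finite, nonzero variance).
#' @return List: r, p, n, df.
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 3L || any(!is.finite(c(x, y)))) stop("need >= 3 finite pairs")
  if (sd(x) == 0 || sd(y) == 0) stop("zero variance input")
  ct <- cor.test(x, y, method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = length(x),
       df = unname(ct$parameter))
}
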