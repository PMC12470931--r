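# Continuous method-agreement statistics: Bland-Altman, Passing-Bablok,
# one-way random-effects ICC with exact F confidence intervals, Spearman,
# RMSE, and Wilcoxon tests. All procedures are authored here; base R
# distribution functions (pt, qf, psignrank, pwilcox, pnorm) supply the
# reference distributions.

check_pairs <- function(x, y, min_n = 3L) {
  if (length(x) != length(y))
    stop_ffrct("x and y must have equal length", class = "ffrct_stats_error")
  ok <- is.finite(x) & is.finite(y)
  if (!all(ok))
    stop_ffrct("non-finite values in paired measurements", class = "ffrct_stats_error")
  if (length(x) < min_n)
    stop_ffrct("need at least %d pairs (got %d)", min_n, length(x),
               class = "ffrct_stats_error")
  invisible(TRUE)
}

#' Bland-Altman analysis
#'
#' Differences are `d = y - x` (candidate minus reference). Reports the
#' mean difference (bias), the sample standard deviation of the
#' differences, the 95% limits of agreement `mean +/- 1.96 * SD`, and the
#' two-sided one-sample t-test p-value for zero mean difference.
#'
#' @param x reference measurements (e.g. invasive FFR)
#' @param y candidate measurements (e.g. FFR-CT)
#' @return object of class `bland_altman` with fields `mean_diff`,
#'   `sd_diff`, `loa_low`, `loa_high`, `p_mean_zero`, `n`
#' @export
bland_altman <- function(x, y) {
  check_pairs(x, y)
  d <- y - x
  n <- length(d)
  m <- mean(d)
  s <- stats::sd(d)
  p <- if (s == 0) {
    if (m == 0) 1 else 0
  } else {
    tt <- m / (s / sqrt(n))
    2 * stats::pt(-abs(tt), df = n - 1)
  }
  structure(list(mean_diff = m, sd_diff = s,
                 loa_low = m - 1.96 * s, loa_high = m + 1.96 * s,
                 p_mean_zero = p, n = n),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman: mean diff %.4f (p = %.3f), 95%% LOA %.3f to %.3f (n = %d)\n",
              x$mean_diff, x$p_mean_zero, x$loa_low, x$loa_high, x$n))
  invisible(x)
}

#' Passing-Bablok regression
#'
#' Nonparametric method-comparison regression following the original 1983
#' procedure: all pairwise slopes `S_ij` (i < j) are formed, slopes equal
#' to -1 exactly are excluded, pairs with identical x and y are skipped,
#' and pairs with equal x count as +/- infinity by the sign of the y
#' difference. With `K` the number of slopes below -1, the slope estimate
#' is the shifted median at rank offset `K`; its confidence interval uses
#' the rank offsets `C = z * sqrt(n(n-1)(2n+5)/18)` with the lower rank
#' floored and the upper rank ceiled. The intercept is
#' `median(y - slope * x)`, with its CI evaluated at the slope CI
#' endpoints.
#'
#' @param x reference method values
#' @param y candidate method values
#' @param conf confidence level, default 0.95
#' @return object of class `passing_bablok` with `slope`, `slope_ci`,
#'   `intercept`, `intercept_ci`, `n`, `n_slopes`
#' @export
passing_bablok <- function(x, y, conf = 0.95) {
  check_pairs(x, y)
  n <- length(x)
  if (n < 10)
    warning("Passing-Bablok regression with fewer than 10 pairs is unstable")
  if (length(unique(x)) == 1L)
    stop_ffrct("all x identical; slope undefined", class = "ffrct_stats_error")
  ij <- utils::combn(n, 2)
  dx <- x[ij[2, ]] - x[ij[1, ]]
  dy <- y[ij[2, ]] - y[ij[1, ]]
  slopes <- ifelse(dx != 0, dy / dx, ifelse(dy > 0, Inf, ifelse(dy < 0, -Inf, NA)))
  slopes <- slopes[!(dx == 0 & dy == 0)]          # identical pairs: skip
  slopes <- slopes[!is.na(slopes) & slopes != -1]  # exclude exact -1
  N <- length(slopes)
  if (N < 3L)
    stop_ffrct("fewer than 3 valid pairwise slopes", class = "ffrct_stats_error")
  slopes <- sort(slopes)
  K <- sum(slopes < -1)
  slope <- shifted_median(slopes, K)
  z <- stats::qnorm(1 - (1 - conf) / 2)
  C <- z * sqrt(n * (n - 1) * (2 * n + 5) / 18)
  m1 <- max(1L, min(N, floor((N - C) / 2) + K))
  m2 <- max(1L, min(N, ceiling((N + C) / 2) + K))
  slope_ci <- c(slopes[m1], slopes[m2])
  intercept <- stats::median(y - slope * x)
  intercept_ci <- sort(c(stats::median(y - slope_ci[2] * x),
                         stats::median(y - slope_ci[1] * x)))
  structure(list(slope = slope, slope_ci = slope_ci, intercept = intercept,
                 intercept_ci = intercept_ci, n = n, n_slopes = N,
                 conf = conf),
            class = "passing_bablok")
}

# median of a sorted vector at rank offset K (the Passing-Bablok shift)
shifted_median <- function(sorted_vals, K) {
  N <- length(sorted_vals)
  if (N %% 2 == 1) {
    sorted_vals[min(N, (N + 1) %/% 2 + K)]
  } else {
    i <- min(N - 1L, N %/% 2 + K)
    (sorted_vals[i] + sorted_vals[i + 1L]) / 2
  }
}

#' @export
print.passing_bablok <- function(x, ...) {
  cat(sprintf("Passing-Bablok: slope %.3f (%.0f%% CI %.3f-%.3f), intercept %.3f (CI %.3f-%.3f), n = %d\n",
              x$slope, 100 * x$conf, x$slope_ci[1], x$slope_ci[2],
              x$intercept, x$intercept_ci[1], x$intercept_ci[2], x$n))
  invisible(x)
}

#' One-way random-effects intraclass correlation, ICC(1,1)
#'
#' From the one-way ANOVA decomposition of an n-subjects by k-ratings
#' matrix: `ICC = (MSB - MSW) / (MSB + (k-1) MSW)`. The exact confidence
#' interval uses `F = MSB/MSW` with
#' `F_L = F / qf(1-a/2; n-1, n(k-1))`, `F_U = F * qf(1-a/2; n(k-1), n-1)`
#' and bounds `(F_L - 1)/(F_L + k - 1)`, `(F_U - 1)/(F_U + k - 1)`.
#'
#' @param ratings numeric matrix, n subjects x k ratings, no missing cells
#' @param conf confidence level, default 0.95
#' @return object of class `icc_result` with `icc`, `ci_low`, `ci_high`,
#'   `msb`, `msw`, `n`, `k`, `model = "one-way random"`
#' @export
icc_oneway <- function(ratings, conf = 0.95) {
  ratings <- as.matrix(ratings)
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 2L || k < 2L)
    stop_ffrct("ICC needs at least 2 subjects and 2 ratings", class = "ffrct_stats_error")
  if (any(!is.finite(ratings)))
    stop_ffrct("missing cells in ratings matrix", class = "ffrct_stats_error")
  row_means <- rowMeans(ratings)
  grand <- mean(ratings)
  msb <- k * sum((row_means - grand)^2) / (n - 1)
  msw <- sum((ratings - row_means)^2) / (n * (k - 1))
  if (msw == 0) {
    icc <- 1
    ci <- c(1, 1)
  } else {
    icc <- (msb - msw) / (msb + (k - 1) * msw)
    a <- 1 - conf
    Fv <- msb / msw
    fl <- Fv / stats::qf(1 - a / 2, n - 1, n * (k - 1))
    fu <- Fv * stats::qf(1 - a / 2, n * (k - 1), n - 1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  }
  structure(list(icc = icc, ci_low = ci[1], ci_high = ci[2], msb = msb,
                 msw = msw, n = n, k = k, conf = conf,
                 model = "one-way random"),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(1,1) = %.3f (%.0f%% CI %.3f-%.3f), n = %d, k = %d\n",
              x$icc, 100 * x$conf, x$ci_low, x$ci_high, x$n, x$k))
  invisible(x)
}

#' Expected confidence-interval width for a one-way ICC
#'
#' Plugs the population value `F = (1 + (k-1) icc) / (1 - icc)` into the
#' exact one-way interval with degrees of freedom `(n-1, n(k-1))` and
#' returns the upper bound minus the lower bound. This is the quantity a
#' precision-based sample-size calculation fixes: for example 19 subjects
#' rated twice give an 80% interval of width 0.389 around an ICC of 0.600.
#'
#' @param n number of subjects
#' @param k ratings per subject
#' @param icc assumed ICC, in (-1/(k-1), 1)
#' @param conf confidence level
#' @return interval width (upper minus lower)
#' @export
icc_ci_width <- function(n, k, icc, conf = 0.95) {
  if (n < 2L || k < 2L)
    stop_ffrct("need n >= 2 and k >= 2", class = "ffrct_stats_error")
  if (!(icc > -1 / (k - 1) && icc < 1))
    stop_ffrct("icc must lie in (-1/(k-1), 1)", class = "ffrct_stats_error")
  a <- 1 - conf
  Fv <- (1 + (k - 1) * icc) / (1 - icc)
  fl <- Fv / stats::qf(1 - a / 2, n - 1, n * (k - 1))
  fu <- Fv * stats::qf(1 - a / 2, n * (k - 1), n - 1)
  (fu - 1) / (fu + k - 1) - (fl - 1) / (fl + k - 1)
}

#' Minimum enrolment after dropout inflation
#'
#' Inflates a required sample size by an anticipated dropout rate,
#' rounding up to whole cases: `ceiling(n / (1 - dropout))`.
#'
#' @param n required analyzable cases
#' @param dropout anticipated dropout fraction in `[0, 1)`
#' @return integer minimum enrolment
#' @export
inflate_for_dropout <- function(n, dropout = 0.2) {
  stopifnot(n > 0, dropout >= 0, dropout < 1)
  as.integer(ceiling(n / (1 - dropout)))
}

#' Spearman rank correlation
#'
#' Midrank-based rho with the t-approximation p-value
#' `t = rho * sqrt((n-2)/(1-rho^2))` on n-2 degrees of freedom.
#'
#' @param x,y paired measurements
#' @return list with `rho`, `p`, `n`
#' @export
spearman_cor <- function(x, y) {
  check_pairs(x, y)
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop_ffrct("rho undefined for constant input", class = "ffrct_stats_error")
  rx <- rank(x)
  ry <- rank(y)
  rho <- sum((rx - mean(rx)) * (ry - mean(ry))) /
    sqrt(sum((rx - mean(rx))^2) * sum((ry - mean(ry))^2))
  n <- length(x)
  p <- if (abs(rho) >= 1) 0 else {
    tt <- rho * sqrt((n - 2) / (1 - rho^2))
    2 * stats::pt(-abs(tt), df = n - 2)
  }
  list(rho = rho, p = p, n = n)
}

#' Root mean square error
#'
#' @param x reference values
#' @param y candidate values
#' @return `sqrt(mean((y - x)^2))`
#' @export
rmse <- function(x, y) {
  check_pairs(x, y, min_n = 1L)
  sqrt(mean((y - x)^2))
}

#' Wilcoxon signed-rank test (paired)
#'
#' Two-sided test of symmetric zero median of the paired differences.
#' Zero differences are dropped; the exact signed-rank distribution is
#' used for n <= 25 without ties in the absolute differences, otherwise
#' the normal approximation with tie correction and continuity correction.
#'
#' @param x,y paired measurements (or `y = NULL` to test `x` directly)
#' @return list with `statistic` (V), `p`, `n_used`, `exact`
#' @export
wilcoxon_signed_rank <- function(x, y = NULL) {
  d <- if (is.null(y)) x else x - y
  d <- d[is.finite(d) & d != 0]
  n <- length(d)
  if (n == 0L) return(list(statistic = 0, p = 1, n_used = 0L, exact = TRUE))
  r <- rank(abs(d))
  v <- sum(r[d > 0])
  ties <- any(duplicated(abs(d)))
  if (n <= 25 && !ties) {
    p_low <- stats::psignrank(v, n)
    p_high <- stats::psignrank(v - 1, n, lower.tail = FALSE)
    p <- min(1, 2 * min(p_low, p_high))
    list(statistic = v, p = p, n_used = n, exact = TRUE)
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (v - mu - sign(v - mu) * 0.5) / sqrt(sig2)
    list(statistic = v, p = min(1, 2 * stats::pnorm(-abs(z))),
         n_used = n, exact = FALSE)
  }
}

#' Wilcoxon rank-sum test (two independent samples)
#'
#' Two-sided Mann-Whitney test. Exact null distribution when both samples
#' have at most 25 observations and there are no ties, otherwise the
#' normal approximation with tie correction and continuity correction.
#'
#' @param a,b numeric samples
#' @return list with `statistic` (W, Mann-Whitney U of `a`), `p`, `exact`
#' @export
wilcoxon_rank_sum <- function(a, b) {
  a <- a[is.finite(a)]
  b <- b[is.finite(b)]
  n1 <- length(a)
  n2 <- length(b)
  if (n1 == 0L || n2 == 0L)
    stop_ffrct("both samples must be non-empty", class = "ffrct_stats_error")
  r <- rank(c(a, b))
  w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- any(duplicated(c(a, b)))
  if (n1 <= 25 && n2 <= 25 && !ties) {
    p_low <- stats::pwilcox(w, n1, n2)
    p_high <- stats::pwilcox(w - 1, n1, n2, lower.tail = FALSE)
    p <- min(1, 2 * min(p_low, p_high))
    list(statistic = w, p = p, exact = TRUE)
  } else {
    mu <- n1 * n2 / 2
    nn <- n1 + n2
    tie_tab <- table(r)
    sig2 <- n1 * n2 / 12 * (nn + 1 - sum(tie_tab^3 - tie_tab) / (nn * (nn - 1)))
    z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sig2)
    list(statistic = w, p = min(1, 2 * stats::pnorm(-abs(z))), exact = FALSE)
  }
}
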