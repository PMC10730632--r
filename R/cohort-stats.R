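#' Interobserver agreement: intraclass correlation coefficient
#'
#' Two-way random-effects, single-rater ICC from the two-way ANOVA
#' decomposition, with an F-based 95\% confidence interval. The default
#' `"agreement"` form (ICC(2,1), absolute agreement) penalizes a systematic
#' offset between observers; `"consistency"` (ICC(3,1)) does not.
#'
#' @param observer_a,observer_b per-subject measurements by the two
#'   observers, same length (>= 3) and order.
#' @param type `"agreement"` (default) or `"consistency"`.
#' @param conf confidence level.
#' @return list with `icc`, `ci_lo`, `ci_hi`, `type`.
#' @export
icc_absolute_agreement <- function(observer_a, observer_b,
                                   type = c("agreement", "consistency"),
                                   conf = 0.95) {
  type <- match.arg(type)
  if (length(observer_a) != length(observer_b)) {
    stop("observers must rate the same subjects")
  }
  if (anyNA(observer_a) || anyNA(observer_b)) stop("missing ratings")
  n <- length(observer_a)
  if (n < 3) stop("need at least 3 subjects")
  k <- 2
  x <- cbind(observer_a, observer_b)
  row_means <- rowMeans(x)
  col_means <- colMeans(x)
  grand <- mean(x)
  msr <- k * stats::var(row_means)                     # between subjects
  msc <- n * sum((col_means - grand)^2) / (k - 1)      # between raters
  sse <- sum((x - outer(row_means, rep(1, k)) -
                outer(rep(1, n), col_means) + grand)^2)
  mse <- sse / ((n - 1) * (k - 1))
  if (msr < 1e-12) {
    warning("zero between-subject variance: ICC degenerate")
    return(list(icc = 0, ci_lo = NA_real_, ci_hi = NA_real_, type = type))
  }
  alpha <- 1 - conf
  if (type == "consistency") {
    icc <- (msr - mse) / (msr + (k - 1) * mse)
    f <- msr / mse
    fl <- f / stats::qf(1 - alpha / 2, n - 1, (n - 1) * (k - 1))
    fu <- f * stats::qf(1 - alpha / 2, (n - 1) * (k - 1), n - 1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  } else {
    icc <- (msr - mse) / (msr + (k - 1) * mse + (k / n) * (msc - mse))
    # Satterthwaite df for the agreement-form interval
    a <- (k * icc) / (n * (1 - icc))
    b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
    v <- (a * msc + b * mse)^2 /
      ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
    f1 <- stats::qf(1 - alpha / 2, n - 1, v)
    f2 <- stats::qf(1 - alpha / 2, v, n - 1)
    lo <- n * (msr - f1 * mse) /
      (f1 * (k * msc + (k * n - k - n) * mse) + n * msr)
    hi <- n * (f2 * msr - mse) /
      (k * msc + (k * n - k - n) * mse + n * f2 * msr)
    ci <- c(lo, hi)
  }
  list(icc = icc, ci_lo = ci[1], ci_hi = ci[2], type = type)
}

#' Kruskal-Wallis comparison of feature values across response groups
#'
#' Rank-based test (midranks, standard tie correction) that the groups come
#' from the same distribution; with two groups this is the asymptotic
#' Wilcoxon rank-sum comparison.
#'
#' @param groups list of numeric vectors, one per group (>= 2 non-empty
#'   groups).
#' @return list with `H` (chi-square statistic), `df` and `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) == 0)) {
    stop("every group must be non-empty")
  }
  values <- unlist(groups, use.names = FALSE)
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  kt <- stats::kruskal.test(values, g)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p = kt$p.value)
}
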