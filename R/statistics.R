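# Prevalence per 10,000 with display rounding and disclosure suppression,
# Pearson chi-square on contingency tables, and two-sample t statistics
# (pooled or Welch, from raw samples or published summary statistics).

#' Round half away from zero
#'
#' Display rounding used throughout the report tables (R's `round()`
#' rounds half to even, which does not reproduce published integers such
#' as 25 from 24.67... consistently at the .5 boundary).
#'
#' @param x Numeric vector.
#' @param digits Decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Prevalence per 10,000 with disclosure suppression
#'
#' Rate per 10,000 rounded half-up to an integer. When the unrounded rate
#' falls below `suppression_floor` (default 5 per 10,000) the published
#' value is 0 with `suppressed = TRUE`, so very small cells cannot be
#' recovered from the report.
#'
#' @param numerator,denominator Non-negative counts, `numerator <=
#'   denominator`, `denominator > 0`. Vectorised over `numerator`.
#' @param suppression_floor Rate floor below which the estimate is
#'   suppressed to 0; use 0 to disable.
#' @return Data frame of class `prevalence_estimate`: `numerator`,
#'   `denominator`, `rate` (full precision per 10,000), `per_10000`
#'   (published integer) and `suppressed`.
#' @export
#' @examples
#' prevalence_per_10000(477, 9727)
prevalence_per_10000 <- function(numerator, denominator,
                                 suppression_floor = 5) {
  if (any(denominator <= 0)) stop("denominator must be positive")
  if (any(numerator < 0 | numerator > denominator)) {
    stop("numerator must lie in [0, denominator]")
  }
  rate <- numerator / denominator * 10000
  suppressed <- rate > 0 & rate < suppression_floor
  per <- as.integer(round_half_up(rate))
  per[suppressed] <- 0L
  structure(
    data.frame(numerator = numerator, denominator = denominator,
               rate = rate, per_10000 = per, suppressed = suppressed),
    class = c("prevalence_estimate", "data.frame")
  )
}

#' Pearson chi-square test of independence
#'
#' Pearson statistic with no continuity correction (the published
#' categorical comparisons reproduce only without Yates' correction),
#' `df = (r-1)(c-1)`, two-sided p from the chi-square distribution.
#'
#' @param table Integer matrix of cell counts, at least 2x2, all margins
#'   positive.
#' @return A `dd_test` list: `statistic`, `df`, `p_value`,
#'   `variant = "pearson_chi2"`, `expected`.
#' @export
#' @examples
#' pearson_chi2(matrix(c(182, 48, 212, 34), nrow = 2))
pearson_chi2 <- function(table) {
  table <- as.matrix(table)
  if (nrow(table) < 2 || ncol(table) < 2) {
    stop("contingency table must be at least 2x2")
  }
  if (any(table < 0)) stop("cell counts must be non-negative")
  if (any(rowSums(table) == 0) || any(colSums(table) == 0)) {
    stop("zero margin: expected counts undefined")
  }
  res <- suppressWarnings(stats::chisq.test(table, correct = FALSE))
  structure(
    list(statistic = unname(res$statistic), df = unname(res$parameter),
         p_value = res$p.value, variant = "pearson_chi2",
         expected = res$expected),
    class = "dd_test"
  )
}

as_summary_stats <- function(x, label) {
  if (is.numeric(x) && is.null(names(x)) && length(x) > 3) {
    return(list(mean = mean(x), sd = stats::sd(x), n = length(x), raw = x))
  }
  if (is.numeric(x) && is.null(names(x))) {
    if (length(x) < 2) stop(label, ": need n >= 2 observations")
    return(list(mean = mean(x), sd = stats::sd(x), n = length(x), raw = x))
  }
  x <- as.list(x)
  if (!all(c("mean", "sd", "n") %in% names(x))) {
    stop(label, ": supply a numeric sample or c(mean=, sd=, n=)")
  }
  if (x$n < 2) stop(label, ": need n >= 2")
  if (x$sd <= 0) stop(label, ": sd must be positive")
  list(mean = x$mean, sd = x$sd, n = x$n, raw = NULL)
}

#' Two-sample t test (pooled or Welch)
#'
#' Accepts either raw numeric samples or published summary statistics
#' (`c(mean=, sd=, n=)`), in which case the closed-form statistic is
#' computed. The pooled equal-variance variant is the default, matching
#' the convention of the original analysis software; Welch (with
#' Satterthwaite degrees of freedom) is available by flag.
#'
#' @param group_a,group_b Numeric sample (length >= 2) or `c(mean=, sd=,
#'   n=)`.
#' @param variant `"pooled"` (default) or `"welch"`.
#' @return A `dd_test` list: `statistic`, `df`, `p_value`, `variant`.
#' @export
#' @examples
#' two_sample_t(c(mean = 27.4, sd = 5.7, n = 394),
#'              c(mean = 29.4, sd = 7.1, n = 83))
two_sample_t <- function(group_a, group_b, variant = c("pooled", "welch")) {
  variant <- match.arg(variant)
  a <- as_summary_stats(group_a, "group_a")
  b <- as_summary_stats(group_b, "group_b")
  if (!is.null(a$raw) && !is.null(b$raw)) {
    res <- stats::t.test(a$raw, b$raw, var.equal = variant == "pooled")
    return(structure(
      list(statistic = unname(res$statistic),
           df = unname(res$parameter), p_value = res$p.value,
           variant = paste0("t_", variant)),
      class = "dd_test"
    ))
  }
  if (variant == "pooled") {
    df <- a$n + b$n - 2
    sp2 <- ((a$n - 1) * a$sd^2 + (b$n - 1) * b$sd^2) / df
    t <- (a$mean - b$mean) / sqrt(sp2 * (1 / a$n + 1 / b$n))
  } else {
    va <- a$sd^2 / a$n
    vb <- b$sd^2 / b$n
    t <- (a$mean - b$mean) / sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (a$n - 1) + vb^2 / (b$n - 1))
  }
  structure(
    list(statistic = t, df = df,
         p_value = 2 * stats::pt(-abs(t), df),
         variant = paste0("t_", variant)),
    class = "dd_test"
  )
}

#' @export
print.dd_test <- function(x, ...) {
  cat(sprintf("%s: statistic %.3f", x$variant, x$statistic))
  if (!is.null(x$df)) cat(sprintf(", df %.1f", x$df))
  cat(sprintf(", p %.4f\n", x$p_value))
  invisible(x)
}
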