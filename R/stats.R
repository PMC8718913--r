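# Method-comparison statistics: Bland-Altman agreement, paired TOST
# equivalence, two-way random-effects ICC, and t tests.

#' Bland-Altman agreement analysis
#'
#' For paired measurements the differences `d = x - y` (by convention
#' automated minus visual; pass the columns in the order you want) give
#' the bias `mean(d)`, the sample SD of the differences (`n - 1`
#' denominator), and the classic 95\% limits of agreement
#' `bias +/- 1.96 * sd`.
#'
#' @param x,y paired numeric vectors (e.g. automated and visual work
#'   rates, W).
#' @param multiplier limits-of-agreement multiplier (1.96 for the classic
#'   normal-theory limits).
#' @return A list of class `bland_altman`: `n`, `bias`, `sd_diff`,
#'   `loa_low`, `loa_high`.
#' @examples
#' bland_altman(c(10, 20, 30), c(12, 19, 33))
#' @export
bland_altman <- function(x, y, multiplier = 1.96) {
  if (length(x) != length(y)) stop("x and y must be paired", call. = FALSE)
  n <- length(x)
  if (n < 2) stop("need at least 2 pairs", call. = FALSE)
  d <- x - y
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  structure(list(n = n, bias = bias, sd_diff = sd_diff,
                 loa_low = bias - multiplier * sd_diff,
                 loa_high = bias + multiplier * sd_diff,
                 multiplier = multiplier),
            class = "bland_altman")
}

#' @export
print.bland_altman <- function(x, ...) {
  cat(sprintf("Bland-Altman (n = %d): bias %.2f +/- %.2f, LoA [%.2f, %.2f]\n",
              x$n, x$bias, x$sd_diff, x$loa_low, x$loa_high))
  invisible(x)
}

#' Limits of agreement from a reported bias and SD
#'
#' Recomputes `bias +/- multiplier * sd` from summary numbers, e.g. to
#' check a published interval against its published bias and SD.
#'
#' @param bias mean difference.
#' @param sd_diff SD of the differences.
#' @param multiplier limits multiplier (default 1.96).
#' @return Named vector `c(loa_low, loa_high)`.
#' @export
loa_from_summary <- function(bias, sd_diff, multiplier = 1.96) {
  c(loa_low = bias - multiplier * sd_diff,
    loa_high = bias + multiplier * sd_diff)
}

#' Paired TOST equivalence test
#'
#' Two one-sided tests of the paired differences against the equivalence
#' bounds `(-bound, +bound)`: `t_lower = (mean + bound) / se` is tested
#' against the upper tail and `t_upper = (mean - bound) / se` against the
#' lower tail, each with `df = n - 1`; the equivalence p value is the
#' larger of the two one-sided p values, and equivalence is declared when
#' it is below `alpha`. Both one-sided statistics are always reported.
#'
#' With zero-variance differences the test degenerates: a mean strictly
#' inside the bounds is reported equivalent with `p_equiv` at the smallest
#' positive double, a mean on or outside the bounds as not equivalent.
#'
#' @param diffs paired differences (e.g. automated - visual, W).
#' @param bound positive equivalence bound (same units as `diffs`).
#' @param alpha significance level.
#' @return A list of class `tost_result`: `t_lower`, `t_upper`, `df`,
#'   `p_lower`, `p_upper`, `p_equiv`, `equivalent`, plus the inputs.
#' @examples
#' d <- as.numeric(scale(1:25)) * 10  # mean 0, sd 10, n 25
#' tost_paired(d, bound = 25)         # t = +/- 12.5, df 24
#' @export
tost_paired <- function(diffs, bound = 25, alpha = 0.05) {
  n <- length(diffs)
  if (n < 2) stop("need at least 2 differences", call. = FALSE)
  if (bound <= 0) stop("bound must be positive", call. = FALSE)
  m <- mean(diffs)
  s <- stats::sd(diffs)
  df <- n - 1
  if (s == 0) {
    inside <- abs(m) < bound
    return(structure(list(
      t_lower = if (m > -bound) Inf else -Inf,
      t_upper = if (m < bound) -Inf else Inf,
      df = df,
      p_lower = if (m > -bound) 0 else 1,
      p_upper = if (m < bound) 0 else 1,
      p_equiv = if (inside) .Machine$double.xmin else 1,
      equivalent = inside, mean_diff = m, sd_diff = s, n = n,
      bound = bound, alpha = alpha), class = "tost_result"))
  }
  se <- s / sqrt(n)
  t_lower <- (m + bound) / se
  t_upper <- (m - bound) / se
  p_lower <- stats::pt(t_lower, df, lower.tail = FALSE)
  p_upper <- stats::pt(t_upper, df, lower.tail = TRUE)
  p_equiv <- max(p_lower, p_upper)
  structure(list(t_lower = t_lower, t_upper = t_upper, df = df,
                 p_lower = p_lower, p_upper = p_upper, p_equiv = p_equiv,
                 equivalent = p_equiv < alpha, mean_diff = m, sd_diff = s,
                 n = n, bound = bound, alpha = alpha),
            class = "tost_result")
}

#' @export
print.tost_result <- function(x, ...) {
  cat(sprintf("Paired TOST vs +/-%g: t_lower(%d) = %.3f, t_upper(%d) = %.3f, p = %.4g -> %s\n",
              x$bound, x$df, x$t_lower, x$df, x$t_upper, x$p_equiv,
              if (x$equivalent) "equivalent" else "not equivalent"))
  invisible(x)
}

#' Intraclass correlation, two-way random effects, absolute agreement
#'
#' The single-rater absolute-agreement ICC -- ICC(2,1) in the
#' Shrout-Fleiss naming, ICC(A,1) in McGraw-Wong -- computed from the
#' two-way ANOVA mean squares as
#' `(MSR - MSE) / (MSR + (k - 1) MSE + k (MSC - MSE) / n)`
#' with `n` subjects and `k` raters; the confidence interval uses the
#' F-distribution method of McGraw and Wong. This is the form for
#' comparing the absolute values of two fixed measurement methods.
#'
#' @param ratings numeric matrix, `n` subjects by `k` raters/methods, no
#'   missing cells.
#' @param conf_level confidence level of the interval.
#' @return A list of class `icc_result`: `icc`, `ci_low`, `ci_high`, `n`,
#'   `k`, and the mean squares `msr`, `msc`, `mse`.
#' @examples
#' m <- cbind(c(1, 3, 5, 7), c(2, 4, 6, 8))
#' icc_agreement(m)
#' @export
icc_agreement <- function(ratings, conf_level = 0.95) {
  ratings <- as.matrix(ratings)
  if (any(is.na(ratings))) stop("no missing cells allowed", call. = FALSE)
  n <- nrow(ratings)
  k <- ncol(ratings)
  if (n < 3 || k < 2) stop("need at least 3 subjects and 2 raters", call. = FALSE)
  if (stats::var(as.vector(ratings)) == 0) {
    stop("ICC undefined: zero total variance", call. = FALSE)
  }
  if (max(abs(ratings - ratings[, 1])) == 0) {
    # all raters identical: perfect agreement, interval degenerates
    return(structure(list(icc = 1, ci_low = 1, ci_high = 1,
                          conf_level = conf_level, n = n, k = k,
                          msr = k * stats::var(ratings[, 1]), msc = 0, mse = 0),
                     class = "icc_result"))
  }
  d <- data.frame(y = as.vector(ratings),
                  subject = factor(rep(seq_len(n), k)),
                  rater = factor(rep(seq_len(k), each = n)))
  # only the mean squares are needed; silence the F-test reliability warning
  # that anova.lm emits when the two-way fit is (near-)exact
  ms <- suppressWarnings(
    stats::anova(stats::aov(y ~ subject + rater, data = d))[["Mean Sq"]])
  msr <- ms[1]
  msc <- ms[2]
  mse <- ms[3]
  icc <- (msr - mse) / (msr + (k - 1) * mse + k * (msc - mse) / n)
  alpha <- 1 - conf_level
  a <- (k * icc) / (n * (1 - icc))
  b <- 1 + (k * icc * (n - 1)) / (n * (1 - icc))
  v <- (a * msc + b * mse)^2 /
    ((a * msc)^2 / (k - 1) + (b * mse)^2 / ((n - 1) * (k - 1)))
  f_l <- stats::qf(1 - alpha / 2, n - 1, v)
  f_u <- stats::qf(1 - alpha / 2, v, n - 1)
  ci_low <- n * (msr - f_l * mse) /
    (f_l * (k * msc + (k * n - k - n) * mse) + n * msr)
  ci_high <- n * (f_u * msr - mse) /
    (k * msc + (k * n - k - n) * mse + n * f_u * msr)
  structure(list(icc = icc, ci_low = ci_low, ci_high = ci_high,
                 conf_level = conf_level, n = n, k = k,
                 msr = msr, msc = msc, mse = mse),
            class = "icc_result")
}

#' @export
print.icc_result <- function(x, ...) {
  cat(sprintf("ICC(2,1) absolute agreement: %.3f (%d%% CI %.3f-%.3f; n = %d, k = %d)\n",
              x$icc, round(100 * x$conf_level), x$ci_low, x$ci_high, x$n, x$k))
  invisible(x)
}

#' Student t test between two methods or groups
#'
#' A thin wrapper over [stats::t.test()] using the pooled-variance
#' (classical Student) form for independent samples and the paired form
#' otherwise, with an explicit error for degenerate (zero-variance)
#' input instead of a misleading statistic.
#'
#' @param x,y numeric vectors; paired when `paired = TRUE`.
#' @param paired compare as paired samples?
#' @return A list with `statistic`, `df`, `p_value`, `method`.
#' @export
method_t_test <- function(x, y, paired = FALSE) {
  if (length(x) < 2 || length(y) < 2) stop("need n >= 2 per group", call. = FALSE)
  if (paired) {
    if (length(x) != length(y)) stop("paired vectors differ in length", call. = FALSE)
    if (stats::sd(x - y) == 0 && mean(x - y) != 0) {
      stop("degenerate paired differences: constant nonzero difference",
           call. = FALSE)
    }
    if (stats::sd(x - y) == 0 && mean(x - y) == 0) {
      return(list(statistic = 0, df = length(x) - 1, p_value = 1,
                  method = "paired t"))
    }
    tt <- stats::t.test(x, y, paired = TRUE)
  } else {
    if (stats::sd(x) == 0 && stats::sd(y) == 0) {
      if (mean(x) != mean(y)) {
        stop("degenerate input: both groups constant", call. = FALSE)
      }
      return(list(statistic = 0, df = length(x) + length(y) - 2, p_value = 1,
                  method = "pooled-variance t"))
    }
    tt <- stats::t.test(x, y, var.equal = TRUE)
  }
  list(statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value,
       method = if (paired) "paired t" else "pooled-variance t")
}

#' Full agreement report between two measurement methods
#'
#' Bundles [bland_altman()], [tost_paired()], [icc_agreement()] and the
#' paired [method_t_test()] for one set of pairs, as used when comparing
#' automated against visual threshold work rates.
#'
#' @param x,y paired values; differences are taken as `x - y`
#'   (by convention automated minus visual).
#' @param bound TOST equivalence bound (W).
#' @param alpha significance level for the TOST.
#' @param direction label recording the difference convention.
#' @return A list of class `agreement_report` with elements
#'   `bland_altman`, `tost`, `icc`, `t_test`, `n`, `direction`.
#' @export
agreement_report <- function(x, y, bound = 25, alpha = 0.05,
                             direction = "x - y") {
  ba <- bland_altman(x, y)
  structure(list(
    n = ba$n,
    bland_altman = ba,
    tost = tost_paired(x - y, bound = bound, alpha = alpha),
    icc = icc_agreement(cbind(x, y)),
    t_test = method_t_test(x, y, paired = TRUE),
    direction = direction), class = "agreement_report")
}

#' @export
print.agreement_report <- function(x, ...) {
  cat(sprintf("Agreement report (n = %d pairs, differences = %s)\n",
              x$n, x$direction))
  print(x$bland_altman)
  print(x$tost)
  print(x$icc)
  cat(sprintf("paired t(%d) = %.3f, p = %.4g\n",
              x$t_test$df, x$t_test$statistic, x$t_test$p_value))
  invisible(x)
}
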