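# Rounding-aware p-value recomputation.
#
# A statistic printed with d decimals stands for any true value in the
# closed half-ULP interval value +/- 0.5 * 10^-d; the p-values at the two
# endpoints bracket every p the authors could correctly have reported.

#' Half-ULP rounding interval of a printed decimal
#'
#' @param value the printed number.
#' @param decimals count of printed decimal places (>= 0).
#' @return numeric vector `c(low, high)` = `value +/- 0.5 * 10^-decimals`;
#'   both endpoints attainable (closed interval).
#' @examples
#' rounding_interval(2.0, 1)   # c(1.95, 2.05)
#' rounding_interval(4.48, 2)  # c(4.475, 4.485)
#' @export
rounding_interval <- function(value, decimals) {
  stopifnot(all(decimals >= 0))
  h <- 0.5 * 10^(-decimals)
  cbind(low = value - h, high = value + h)[, , drop = TRUE]
}

.symmetric <- c("t", "r", "Z")

# smallest positive double: tail probabilities are computed in the
# numerically stable upper-tail form and clamped away from exact zero
.p_floor <- .Machine$double.xmin

#' Tail probability of a test statistic
#'
#' Recomputes the p-value implied by a printed statistic and its degrees of
#' freedom. All tests are two-tailed by default: t, r, and Z use the
#' two-sided tail of the symmetric distribution; F and chi-squared are
#' inherently one-sided upper-tail tests. A correlation r is converted to
#' `t = r * sqrt(df / (1 - r^2))` on `df` degrees of freedom (the exact test
#' under bivariate normality, with the APA convention df = N - 2) and
#' handled as a t. `tails = "one"` halves the two-tailed value and is only
#' meaningful for the symmetric families; requesting it for F or
#' chi-squared is an error.
#'
#' @param family one of `"t"`, `"F"`, `"r"`, `"chi2"`, `"Z"` (vectorized).
#' @param stat the test statistic.
#' @param df1,df2 degrees of freedom as the family requires (`df1` for F and
#'   chi-squared, `df2` for t, F, and r; neither for Z).
#' @param tails `"two"` (default) or `"one"`.
#' @return the recomputed p-value, in (0, 1].
#' @examples
#' p_from_stat("t", 2.0, df2 = 28)          # 0.0553 -> prints as .055
#' p_from_stat("F", 4.48, df1 = 2, df2 = 70)
#' @export
p_from_stat <- function(family, stat, df1 = NA_real_, df2 = NA_real_,
                        tails = c("two", "one")) {
  tails <- match.arg(tails)
  n <- max(length(family), length(stat), length(df1), length(df2))
  family <- rep_len(family, n)
  stat <- rep_len(stat, n)
  df1 <- rep_len(as.numeric(df1), n)
  df2 <- rep_len(as.numeric(df2), n)

  if (tails == "one" && any(family %in% c("F", "chi2"))) {
    stop("one-tailed recomputation is undefined for F and chi2: ",
         "these are inherently upper-tail tests")
  }
  if (any(family == "r" & !is.na(stat) & abs(stat) >= 1)) {
    stop("|r| >= 1 is outside the domain of the correlation test")
  }
  need_df2 <- family %in% c("t", "r", "F")
  need_df1 <- family %in% c("F", "chi2")
  if (any(need_df2 & (is.na(df2) | df2 <= 0)) ||
      any(need_df1 & (is.na(df1) | df1 <= 0))) {
    stop("degrees of freedom must be present and > 0 for the family")
  }

  p <- rep(NA_real_, n)
  i <- family == "t"
  if (any(i)) p[i] <- 2 * stats::pt(abs(stat[i]), df2[i], lower.tail = FALSE)
  i <- family == "r"
  if (any(i)) {
    tv <- stat[i] * sqrt(df2[i] / (1 - stat[i]^2))
    p[i] <- 2 * stats::pt(abs(tv), df2[i], lower.tail = FALSE)
  }
  i <- family == "F"
  if (any(i)) p[i] <- stats::pf(stat[i], df1[i], df2[i], lower.tail = FALSE)
  i <- family == "chi2"
  if (any(i)) p[i] <- stats::pchisq(stat[i], df1[i], lower.tail = FALSE)
  i <- family == "Z"
  if (any(i)) p[i] <- 2 * stats::pnorm(abs(stat[i]), lower.tail = FALSE)

  if (tails == "one") p <- p / 2
  pmin(pmax(p, .p_floor), 1)
}

#' Recompute the p-interval for one extracted result
#'
#' Computes the point p-value at the printed statistic and the interval of
#' p-values induced by half-ULP rounding of the printed statistic. For the
#' symmetric families the interval is taken on |statistic|, so a printed
#' negative value yields the same interval as its positive twin; an
#' absolute rounding bound that crosses zero maps to p = 1.
#'
#' @param result one row of an [extract_results()] data.frame (or a list
#'   with the same fields).
#' @param tails `"two"` (default) or `"one"`.
#' @return a list of class `p_interval`: `p_point`, `p_low`, `p_high`,
#'   `tails`, with `0 < p_low <= p_point <= p_high <= 1`.
#' @examples
#' res <- extract_results("t(28) = 2.0, p < .05")
#' recompute_p(res[1, ])
#' @export
recompute_p <- function(result, tails = c("two", "one")) {
  tails <- match.arg(tails)
  fam <- result$family
  stat <- result$stat_value
  a <- if (fam %in% .symmetric) abs(stat) else stat
  h <- 0.5 * 10^(-result$stat_decimals)
  lo_stat <- a - h
  hi_stat <- a + h
  if (fam %in% c("F", "chi2", .symmetric)) lo_stat <- max(lo_stat, 0)
  if (fam == "r") hi_stat <- min(hi_stat, 1 - 1e-12)
  p_point <- p_from_stat(fam, a, result$df1, result$df2, tails)
  p_hi <- p_from_stat(fam, lo_stat, result$df1, result$df2, tails)
  p_lo <- p_from_stat(fam, hi_stat, result$df1, result$df2, tails)
  structure(
    list(p_point = p_point,
         p_low = min(p_lo, p_point),
         p_high = max(p_hi, p_point),
         tails = tails),
    class = "p_interval"
  )
}

#' @export
print.p_interval <- function(x, ...) {
  cat(sprintf("<p_interval> p = %.6g in [%.6g, %.6g] (%s-tailed)\n",
              x$p_point, x$p_low, x$p_high, x$tails))
  invisible(x)
}
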