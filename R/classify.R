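# Consistency classification.
#
# A reported p is *compatible* when some value in the recomputed p-interval
# satisfies the reported relation; an incompatible report is an
# inconsistency, and a gross inconsistency when it also flips the
# statistical conclusion at alpha.

#' Consistency-checking policy
#'
#' @param alpha significance level used for the gross/consistent conclusion
#'   comparison (default .05).
#' @param p_equal_alpha_is_significant treat "p = .05" (p equal to alpha) as
#'   a claim of significance; default TRUE, following observed reporting
#'   practice in which almost all "p = .05" statements present the result
#'   as significant.
#' @param p_zero_is_error treat "p = .000" as an error regardless of the
#'   recomputed value — a p-value cannot exactly be zero; default TRUE.
#' @param one_tailed_rescue reclassify an otherwise inconsistent symmetric
#'   family result as consistent when the article mentions one-tailed
#'   language and the halved p-value is compatible; default TRUE.
#' @param triggers trigger phrases for the one-tailed scan.
#' @return a list of class `consistency_policy`.
#' @export
consistency_policy <- function(alpha = 0.05,
                               p_equal_alpha_is_significant = TRUE,
                               p_zero_is_error = TRUE,
                               one_tailed_rescue = TRUE,
                               triggers = c("one-tailed", "one-sided",
                                            "directional")) {
  stopifnot(is.numeric(alpha), length(alpha) == 1, alpha > 0, alpha < 1)
  structure(
    list(alpha = alpha,
         p_equal_alpha_is_significant = p_equal_alpha_is_significant,
         p_zero_is_error = p_zero_is_error,
         one_tailed_rescue = one_tailed_rescue,
         triggers = triggers),
    class = "consistency_policy"
  )
}

#' Did the authors present the result as significant?
#'
#' `p < v` with `v <= alpha` and `p = v` with `v <= alpha` claim
#' significance (the latter is the "p = .05 counts as significant" rule);
#' `p = v` with `v > alpha`, `p > v` with `v >= alpha`, and `ns` claim
#' nonsignificance. A greater-than bound below alpha (e.g. "p > .01")
#' asserts neither and returns `NA`: such reports can be inconsistent but
#' never gross, since gross requires an unambiguous significance claim.
#'
#' @param result one or more rows of an [extract_results()] data.frame.
#' @param policy a [consistency_policy()].
#' @return logical vector (`NA` = no claim either way).
#' @export
reported_significance <- function(result, policy = consistency_policy()) {
  a <- policy$alpha
  op <- result$p_op
  pv <- result$p_value
  sig <- rep(NA, length(op))
  sig[op == "ns"] <- FALSE
  eq_cut <- if (policy$p_equal_alpha_is_significant) a else a - .Machine$double.eps
  sig[op == "eq"] <- pv[op == "eq"] <= eq_cut
  sig[op == "lt"] <- ifelse(pv[op == "lt"] <= a, TRUE, NA)
  sig[op == "gt"] <- ifelse(pv[op == "gt"] >= a, FALSE, NA)
  sig
}

# vectorized compatibility of reported relations with p-intervals
.compatible <- function(p_op, p_value, p_decimals, p_low, p_high, policy) {
  a <- policy$alpha
  comp <- rep(NA, length(p_op))
  i <- p_op == "lt"
  comp[i] <- p_low[i] < p_value[i]
  i <- p_op == "gt"
  comp[i] <- p_high[i] > p_value[i]
  i <- p_op == "ns"
  comp[i] <- p_high[i] > a
  i <- p_op == "eq"
  if (any(i)) {
    h <- 0.5 * 10^(-p_decimals[i])
    comp[i] <- p_low[i] <= p_value[i] + h & p_high[i] >= p_value[i] - h
  }
  if (policy$p_zero_is_error) {
    comp[p_op == "eq" & p_value == 0] <- FALSE
  }
  comp
}

#' Classify extracted results as consistent, inconsistent, or gross
#'
#' Joins each extracted result with its rounding-aware recomputation and
#' labels it:
#' * `consistent` — some recomputable p satisfies the reported relation
#'   (statistic rounding is honoured; an exactly-reported p additionally
#'   gets its own half-ULP interval);
#' * `inconsistency` — no recomputable p satisfies the report;
#' * `gross_inconsistency` — an inconsistency that flips the conclusion at
#'   alpha (reported significant, computed nonsignificant, or vice versa).
#'
#' When the article mentions one-tailed language, an initially inconsistent
#' t, r, or Z result whose halved (one-tailed) p-value is compatible is
#' rescued to `consistent` with `one_tailed_applied = TRUE`. "p = .000"
#' is always incompatible under the default policy (a p-value cannot be
#' exactly zero). Records whose recomputation hits a domain error (e.g.
#' |r| >= 1) get label `NA` and are excluded from rates, never silently
#' mislabeled.
#'
#' @param results data.frame from [extract_results()] (any number of
#'   articles).
#' @param one_tailed logical: article-level one-tailed mention, either a
#'   single value recycled to all rows or a named vector indexed by
#'   `article_id`.
#' @param policy a [consistency_policy()].
#' @return the input data.frame with columns added: `computed_p`,
#'   `computed_p_low`, `computed_p_high`, `one_tailed_applied`,
#'   `reported_significant`, `computed_significant`, `label`.
#' @examples
#' res <- extract_results("t(28) = 2.0, p < .05 and F(2,56) = 1.203, p < .001")
#' classify_results(res)[, c("family", "p_op", "p_value", "label")]
#' @export
classify_results <- function(results, one_tailed = FALSE,
                             policy = consistency_policy()) {
  n <- nrow(results)
  if (is.null(names(one_tailed))) {
    mentions <- rep_len(one_tailed, n)
  } else {
    mentions <- unname(one_tailed[results$article_id])
    mentions[is.na(mentions)] <- FALSE
  }

  # vectorized recomputation; rows with domain violations (|r| >= 1,
  # missing/nonpositive dfs) are unclassifiable
  fam <- results$family
  sym <- fam %in% .symmetric
  ok <- rep(TRUE, n)
  ok[fam == "r" & abs(results$stat_value) >= 1] <- FALSE
  ok[fam %in% c("t", "r", "F") &
       (is.na(results$df2) | results$df2 <= 0)] <- FALSE
  ok[fam %in% c("F", "chi2") &
       (is.na(results$df1) | results$df1 <= 0)] <- FALSE
  if (any(!ok)) {
    for (i in which(!ok)) {
      message(sprintf("reportcheck [%s]: unclassifiable result '%s'",
                      results$article_id[i], results$raw_span[i]))
    }
  }
  p_point <- p_low <- p_high <- rep(NA_real_, n)
  if (any(ok)) {
    a <- ifelse(sym, abs(results$stat_value), results$stat_value)
    h <- 0.5 * 10^(-results$stat_decimals)
    lo_s <- pmax(a - h, 0)
    hi_s <- ifelse(fam == "r", pmin(a + h, 1 - 1e-12), a + h)
    p_point[ok] <- p_from_stat(fam[ok], a[ok], results$df1[ok],
                               results$df2[ok])
    p_hi <- p_from_stat(fam[ok], lo_s[ok], results$df1[ok], results$df2[ok])
    p_lo <- p_from_stat(fam[ok], hi_s[ok], results$df1[ok], results$df2[ok])
    p_low[ok] <- pmin(p_lo, p_point[ok])
    p_high[ok] <- pmax(p_hi, p_point[ok])
  }

  comp <- .compatible(results$p_op, results$p_value, results$p_decimals,
                      p_low, p_high, policy)
  one_tailed_applied <- rep(FALSE, n)
  rescue <- ok & !comp & policy$one_tailed_rescue & mentions &
    results$family %in% .symmetric
  if (any(rescue)) {
    comp1 <- .compatible(results$p_op[rescue], results$p_value[rescue],
                         results$p_decimals[rescue],
                         p_low[rescue] / 2, p_high[rescue] / 2, policy)
    one_tailed_applied[rescue] <- comp1
    comp[rescue] <- comp[rescue] | comp1
  }

  rep_sig <- reported_significance(results, policy)
  cmp_sig <- p_point <= policy$alpha
  near_tie <- ok & abs(p_point - policy$alpha) < 1e-12
  if (any(near_tie)) {
    message(sprintf(
      "reportcheck: %d recomputed p-value(s) within 1e-12 of alpha",
      sum(near_tie)))
  }

  label <- rep(NA_character_, n)
  label[ok & comp] <- "consistent"
  incons <- ok & !comp
  label[incons] <- ifelse(!is.na(rep_sig[incons]) &
                            rep_sig[incons] != cmp_sig[incons],
                          "gross_inconsistency", "inconsistency")

  results$computed_p <- p_point
  results$computed_p_low <- p_low
  results$computed_p_high <- p_high
  results$one_tailed_applied <- one_tailed_applied
  results$reported_significant <- rep_sig
  results$computed_significant <- cmp_sig
  results$label <- label
  results
}

#' Check one result end to end
#'
#' Convenience wrapper: extract, recompute, and classify a single APA
#' result string (optionally with surrounding prose supplying one-tailed
#' language).
#'
#' @param text a string containing at least one APA-formatted result.
#' @param policy a [consistency_policy()].
#' @return classified data.frame, as [classify_results()].
#' @examples
#' check_text("F(2,56) = 1.203, p < .001")$label
#' @export
check_text <- function(text, policy = consistency_policy()) {
  art <- as_article_text(text)
  classify_results(extract_results(art),
                   one_tailed = detect_one_tailed(art, policy$triggers)$mentions_one_tailed,
                   policy = policy)
}
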