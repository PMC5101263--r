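# build a minimal classified-record frame by hand
mk_records <- function(article_id, label,
                       reported_significant = TRUE,
                       computed_significant = TRUE) {
  data.frame(article_id = article_id, label = label,
             reported_significant = reported_significant,
             computed_significant = computed_significant,
             stringsAsFactors = FALSE)
}

test_that("per-article counts and percentages follow their definitions", {
  r <- mk_records("a1", c(rep("consistent", 9), "inconsistency"))
  s <- summarize_articles(r)
  expect_equal(s$pct_inconsistent, 10)
  expect_equal(s$pct_gross, 0)
  expect_true(s$any_inconsistent)
  expect_false(s$any_gross)

  s2 <- summarize_articles(mk_records("a2", rep("consistent", 4)))
  expect_equal(c(s2$pct_inconsistent, s2$pct_gross), c(0, 0))
  expect_false(s2$any_inconsistent || s2$any_gross)

  # gross is counted inside inconsistent
  s3 <- summarize_articles(mk_records(
    "a3", c("consistent", "inconsistency", "gross_inconsistency")))
  expect_equal(s3$n_inconsistent, 2)
  expect_equal(s3$n_gross, 1)

  expect_error(summarize_articles(mk_records("x", "consistent")[0, ]),
               "no classifiable")
})

test_that("corpus stats: article counts, pooled shares, unweighted rates", {
  r <- rbind(
    mk_records("a1", c(rep("consistent", 10))),                    # 0 %
    mk_records("a2", c("inconsistency", rep("consistent", 4))),    # 20 %
    mk_records("a3", c("gross_inconsistency", "consistent")),      # 50 %
    mk_records("a4", "consistent")                                 # 0 %
  )
  art <- summarize_articles(r)
  cs <- summarize_corpus(art, r)
  expect_equal(cs$n_articles_with_nhst, 4)
  expect_equal(cs$pct_articles_any_inconsistent, 50)
  expect_equal(cs$pct_articles_any_gross, 25)
  expect_equal(cs$pct_results_inconsistent, 100 * 2 / 18)
  expect_equal(cs$pct_results_gross, 100 * 1 / 18)
  # unweighted mean of per-article percentages, not the pooled share
  expect_equal(cs$inconsistency_rate, mean(c(0, 20, 50, 0)))
  expect_equal(cs$gross_rate, mean(c(0, 0, 50, 0)))
  expect_equal(cs$median_results_per_article, median(c(10, 5, 2, 1)))
})

test_that("unweighted-mean semantics are independent of article sizes", {
  r <- rbind(
    mk_records("big", rep("consistent", 80)),                       # 0 %
    mk_records("small", c("inconsistency", rep("consistent", 4)))   # 20 %
  )
  cs <- summarize_corpus(summarize_articles(r), r)
  expect_equal(cs$inconsistency_rate, 10)            # (0 + 20) / 2
  expect_equal(cs$pct_results_inconsistent, 100 / 85)
})

test_that("significance split and empty denominators", {
  r <- rbind(
    mk_records("a1", c("consistent", "gross_inconsistency"),
               reported_significant = TRUE, computed_significant = c(TRUE, FALSE)),
    mk_records("a2", "consistent",
               reported_significant = FALSE, computed_significant = FALSE)
  )
  cs <- summarize_corpus(summarize_articles(r), r)
  expect_equal(cs$pct_reported_significant, 100 * 2 / 3)
  expect_equal(cs$pct_computed_significant, 100 * 1 / 3)
  expect_equal(cs$gross_rate_in_significant, 50)
  expect_equal(cs$gross_rate_in_nonsignificant, 0)

  # all significant: the nonsignificant denominator is absent, not zero
  r2 <- mk_records("a1", rep("consistent", 3))
  cs2 <- summarize_corpus(summarize_articles(r2), r2)
  expect_true(is.na(cs2$gross_rate_in_nonsignificant))
  expect_equal(cs2$gross_rate_in_significant, 0)
})

test_that("conservation: article stats sum to the classified record count", {
  set.seed(21)
  co <- generate_corpus(12, c(2001, 2003), inconsistency_fraction = 0.2,
                        gross_fraction = 0.1, results_per_article = 5,
                        seed = 77)
  rc <- check_articles(articles = co$articles)
  art <- summarize_articles(rc$results)
  expect_equal(sum(art$n_results), sum(!is.na(rc$results$label)))
})

test_that("linear trends: slope, variance explained, and error cases", {
  tr <- yearly_trend(2000:2002, c(10, 12, 14))
  expect_equal(tr$b, 2)
  expect_equal(tr$r2, 1)

  flat <- yearly_trend(2000:2004, rep(7, 5))
  expect_equal(flat$b, 0)
  expect_equal(flat$r2, 0)

  # 5-point series against the hand-solved normal equations
  yr <- c(2000, 2001, 2002, 2003, 2004)
  pct <- c(12, 9, 11, 7, 6)
  b_hand <- sum((yr - mean(yr)) * (pct - mean(pct))) / sum((yr - mean(yr))^2)
  r2_hand <- cor(yr, pct)^2
  tr5 <- yearly_trend(yr, pct)
  expect_equal(tr5$b, b_hand)
  expect_equal(tr5$r2, r2_hand)

  expect_error(yearly_trend(2000, 5), "distinct years")
  expect_error(yearly_trend(c(2000, 2000), c(5, 6)), "distinct years")
})

test_that("grouped summaries concatenate to the ungrouped totals", {
  set.seed(5)
  co <- generate_corpus(10, c(2010, 2011), inconsistency_fraction = 0.2,
                        gross_fraction = 0.1, results_per_article = 5,
                        seed = 42)
  rc <- check_articles(articles = co$articles)
  g <- summarize_groups(rc$results, co$metadata, by = c("journal", "year"))
  cs <- summarize_corpus(summarize_articles(rc$results), rc$results)
  expect_equal(sum(g$n_results), cs$n_results)
  expect_equal(sum(g$n_articles_with_nhst), cs$n_articles_with_nhst)
  expect_equal(sum(g$n_results * g$pct_results_inconsistent) / sum(g$n_results),
               cs$pct_results_inconsistent)
})

test_that("articles missing from metadata land in group 'unknown'", {
  r <- mk_records(c("a1", "a2"), c("consistent", "inconsistency"))
  meta <- data.frame(article_id = "a1", journal = "J1", year = 2000,
                     stringsAsFactors = FALSE)
  expect_message(g <- summarize_groups(r, meta, by = "journal"), "unknown")
  expect_setequal(g$journal, c("J1", "unknown"))
})
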