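test_that("reported significance follows the alpha = .05 conventions", {
  mk <- function(op, pv) data.frame(p_op = op, p_value = pv)
  expect_true(reported_significance(mk("eq", 0.05)))   # p = .05 rule
  expect_true(reported_significance(mk("lt", 0.001)))
  expect_true(reported_significance(mk("lt", 0.05)))
  expect_false(reported_significance(mk("eq", 0.06)))
  expect_false(reported_significance(mk("gt", 0.05)))
  expect_false(reported_significance(mk("ns", NA)))
  # a gt bound below alpha claims neither direction
  expect_true(is.na(reported_significance(mk("gt", 0.01))))
  # the p = .05 rule is policy-switchable
  pol <- consistency_policy(p_equal_alpha_is_significant = FALSE)
  expect_false(reported_significance(mk("eq", 0.05), pol))
})

test_that("worked boundary example: t(28) = 2.0, p < .05 is consistent", {
  r <- check_text("t(28) = 2.0, p < .05")
  expect_equal(r$label, "consistent")
  expect_false(r$computed_significant)   # point p = .055
  expect_true(r$reported_significant)
})

test_that("the dropped-digit typo example is a gross inconsistency", {
  r <- check_text("F(2,56) = 1.203, p < .001")
  expect_equal(r$label, "gross_inconsistency")
  expect_true(r$reported_significant)
  expect_false(r$computed_significant)
  # the intended statistic is consistent
  expect_equal(check_text("F(2,56) = 12.03, p < .001")$label, "consistent")
})

test_that("p = .000 is always flagged; gross only when conclusions flip", {
  # computed significant: stays an (ordinary) inconsistency
  r1 <- check_text("t(37) = -4.93, p = .000")
  expect_equal(r1$label, "inconsistency")
  # computed nonsignificant: flips the conclusion
  r2 <- check_text("t(28) = 1.10, p = .000")
  expect_equal(r2$label, "gross_inconsistency")
  # switching the policy off restores interval semantics
  pol <- consistency_policy(p_zero_is_error = FALSE)
  r3 <- classify_results(extract_results("t(37) = -4.93, p = .000"),
                         policy = pol)
  expect_equal(r3$label, "consistent")  # |t| huge, p_low < .0005
})

test_that("classification truth table matches hand enumeration", {
  # base nonsignificant: t(28) = 2.0 -> p interval [.0498, .0613], point .0553
  cases_nonsig <- list(
    list(p = "p < .05", label = "consistent"),          # .0498 attainable
    list(p = "p < .04", label = "gross_inconsistency"), # sig claim, false
    list(p = "p = .055", label = "consistent"),
    list(p = "p = .3", label = "inconsistency"),        # same side of alpha
    list(p = "p = .04", label = "gross_inconsistency"),
    list(p = "p > .05", label = "consistent"),          # .0613 > .05
    list(p = "p > .07", label = "inconsistency"),       # no sig claim flip
    list(p = "p > .01", label = "consistent"),
    list(p = "ns", label = "consistent")
  )
  for (cs in cases_nonsig) {
    r <- check_text(paste0("t(28) = 2.0, ", cs$p))
    expect_equal(r$label, cs$label, info = cs$p)
  }
  # base significant: t(28) = 3.0 -> p interval ~ [.0049, .0064]
  cases_sig <- list(
    list(p = "p = .006", label = "consistent"),
    list(p = "p < .01", label = "consistent"),
    list(p = "p = .04", label = "inconsistency"),       # sig side, wrong value
    list(p = "ns", label = "gross_inconsistency"),      # ns vs computed sig
    list(p = "p = .20", label = "gross_inconsistency"),
    list(p = "p > .01", label = "inconsistency")        # gt below alpha: never gross
  )
  for (cs in cases_sig) {
    r <- check_text(paste0("t(28) = 3.0, ", cs$p))
    expect_equal(r$label, cs$label, info = cs$p)
  }
})

test_that("one-tailed rescue turns eligible errors consistent, and only that", {
  # t(20) = 1.80: two-tailed interval ~ [.0795, .0868] -> "p < .05" gross;
  # halved one-tailed interval ~ [.0397, .0434] -> compatible
  base <- "t(20) = 1.80, p < .05"
  no_mention <- check_text(base)
  expect_equal(no_mention$label, "gross_inconsistency")
  rescued <- check_text(paste("All tests are one-tailed.", base))
  expect_equal(rescued$label, "consistent")
  expect_true(rescued$one_tailed_applied)
  # rescue never applies to the inherently one-sided families
  f_base <- "F(2, 70) = 2.60, p < .05"
  expect_equal(check_text(f_base)$label,
               check_text(paste("A one-tailed test.", f_base))$label)
  expect_false(check_text(paste("A one-tailed test.", f_base))$one_tailed_applied)
  # rescue is off when the policy disables it
  pol <- consistency_policy(one_tailed_rescue = FALSE)
  r <- classify_results(extract_results(base), one_tailed = TRUE, policy = pol)
  expect_equal(r$label, "gross_inconsistency")
})

test_that("rescue is monotone: labels only improve when mention appears", {
  set.seed(11)
  rank <- c(consistent = 0, inconsistency = 1, gross_inconsistency = 2)
  for (s in 1:6) {
    ga <- generate_article(gen_spec(n_results = 8,
                                    inconsistency_fraction = 0.5,
                                    gross_fraction = 0.25, seed = 300 + s),
                           "mono")
    res <- extract_results(ga$article)
    without <- classify_results(res, one_tailed = FALSE)$label
    with <- classify_results(res, one_tailed = TRUE)$label
    expect_true(all(rank[with] <= rank[without]))
  }
})

test_that("unclassifiable records get NA labels and are excluded from rates", {
  txt <- "r(30) = 1.20, p < .05 and t(28) = 2.0, p < .05"
  expect_message(r <- classify_results(extract_results(txt)),
                 "unclassifiable")
  expect_true(is.na(r$label[1]))
  expect_equal(r$label[2], "consistent")
  art <- summarize_articles(r)
  expect_equal(art$n_results, 1)
})

test_that("classification is deterministic", {
  txt <- paste("t(28) = 2.0, p < .05.", "F(2,56) = 1.203, p < .001.",
               "z = 2.36, p = .018.")
  expect_identical(check_text(txt)$label, check_text(txt)$label)
})
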