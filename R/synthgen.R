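# Synthetic article generator.
#
# Articles carry APA-formatted results with known ground-truth labels:
# seeded inconsistent printed p-values are placed at least one reported-ULP
# outside the compatible interval (no boundary flakiness), gross ones on
# the other side of alpha from the recomputed p. Error counts are
# constructed, not sampled, so seeded prevalences are exact.

#' Specification for one synthetic article
#'
#' @param n_results number of extractable APA results to embed.
#' @param inconsistency_fraction fraction of results printed inconsistently
#'   (gross included).
#' @param gross_fraction fraction of results printed grossly inconsistently
#'   (a subset of the inconsistent fraction; must not exceed it).
#' @param families sampling weights over the five test families.
#' @param one_tailed_mention embed one-tailed language in the prose.
#' @param include_ignorable number of must-ignore strings (effect-size
#'   interposition, compound sentences, table fragments) to add.
#' @param seed integer seed; identical spec + seed gives byte-identical
#'   text.
#' @param n_inconsistent,n_gross optional exact counts overriding the
#'   fractions (used by [generate_corpus()] to make corpus prevalences
#'   exact).
#' @return a list of class `gen_spec`.
#' @export
gen_spec <- function(n_results = 10,
                     inconsistency_fraction = 0,
                     gross_fraction = 0,
                     families = c(t = 0.3, F = 0.3, r = 0.15,
                                  chi2 = 0.15, Z = 0.1),
                     one_tailed_mention = FALSE,
                     include_ignorable = 0,
                     seed = 1L,
                     n_inconsistent = NULL,
                     n_gross = NULL) {
  stopifnot(gross_fraction <= inconsistency_fraction,
            all(families >= 0), sum(families) > 0,
            n_results >= 0)
  structure(
    list(n_results = n_results,
         inconsistency_fraction = inconsistency_fraction,
         gross_fraction = gross_fraction,
         families = families,
         one_tailed_mention = one_tailed_mention,
         include_ignorable = include_ignorable,
         seed = as.integer(seed),
         n_inconsistent = n_inconsistent,
         n_gross = n_gross),
    class = "gen_spec"
  )
}

.draw_params <- function(family) {
  switch(family,
    t = list(df1 = NA_real_, df2 = sample(5:200, 1),
             stat = round(stats::runif(1, 0.2, 5), 2)),
    F = list(df1 = sample(1:6, 1), df2 = sample(10:200, 1),
             stat = round(stats::runif(1, 0.05, 10), 2)),
    r = list(df1 = NA_real_, df2 = sample(10:300, 1),
             stat = round(stats::runif(1, -0.85, 0.85), 2)),
    chi2 = list(df1 = sample(1:10, 1), df2 = NA_real_,
                stat = round(stats::runif(1, 0.1, 25), 2)),
    Z = list(df1 = NA_real_, df2 = NA_real_,
             stat = round(stats::runif(1, -3.5, 3.5), 2))
  )
}

# margins: reported-p half-ULP at 3 decimals is 5e-4; seeded errors sit at
# least .001 beyond the compatible interval, seeded consistents at least
# 1e-6 inside
.EPS_OUT <- 1e-3
.EPS_IN <- 1e-6

# incompatibility of an eq-report pv (3 decimals) with [lo, hi]
.eq_incompatible <- function(pv, lo, hi) {
  pv + 5e-4 < lo - .EPS_OUT | pv - 5e-4 > hi + .EPS_OUT
}

# choose the printed p for one result; NULL when infeasible for this draw
.print_p <- function(target, p_point, p_low, p_high, symmetric,
                     one_tailed_mention) {
  check_rescue <- one_tailed_mention && symmetric
  if (target == "consistent") {
    if (p_high < 0.001 - .EPS_IN) return(list(op = "lt", pv = 0.001))
    if (p_high > 0.05 + 0.005 && stats::runif(1) < 0.15) {
      return(list(op = "ns", pv = NA_real_))
    }
    pv <- round(p_point, 3)
    if (pv <= 0) {
      if (p_low < 0.001 - .EPS_IN) return(list(op = "lt", pv = 0.001))
      return(NULL)
    }
    return(list(op = "eq", pv = pv))
  }
  sig <- p_point <= 0.05
  if (target == "inconsistency") {
    cand <- if (sig) seq(0.001, 0.050, by = 0.001) else seq(0.051, 0.999, by = 0.001)
    ok <- .eq_incompatible(cand, p_low, p_high)
    if (check_rescue) ok <- ok & .eq_incompatible(cand, p_low / 2, p_high / 2)
    cand <- cand[ok]
    if (!length(cand)) return(NULL)
    return(list(op = "eq", pv = sample(cand, 1)))
  }
  # gross: printed significance must contradict the computed one
  if (sig) {
    cand <- seq(0.06, 0.99, by = 0.01)
    ok <- cand - 5e-4 > p_high + .EPS_OUT  # halving only lowers the interval
    cand <- cand[ok]
    if (!length(cand)) return(NULL)
    return(list(op = "eq", pv = sample(cand, 1)))
  }
  if (p_low > 0.0015 + .EPS_OUT &&
      (!check_rescue || p_low / 2 > 0.0015 + .EPS_OUT) &&
      stats::runif(1) < 0.3) {
    return(list(op = "lt", pv = 0.001))  # the classic dropped-digit typo
  }
  cand <- seq(0.001, 0.049, by = 0.001)
  ok <- cand + 5e-4 < p_low - .EPS_OUT
  if (check_rescue) ok <- ok & .eq_incompatible(cand, p_low / 2, p_high / 2)
  cand <- cand[ok]
  if (!length(cand)) return(NULL)
  list(op = "eq", pv = sample(cand, 1))
}

.fmt_p <- function(pv, strip_zero = TRUE) {
  s <- sprintf("%.3f", pv)
  if (strip_zero) s <- sub("^0", "", s)
  s
}

.fmt_stat <- function(family, stat) {
  s <- sprintf("%.2f", stat)
  if (family == "r" && stats::runif(1) < 0.5) s <- sub("^(-?)0", "\\1", s)
  s
}

.op_sym <- c(lt = "<", gt = ">", eq = "=")

# render one result in plain text and (optionally) simple HTML, with
# randomized APA-legal spacing
.render_result <- function(family, df1, df2, n_rep, stat_s, p) {
  stat_part <- switch(family,
    t = sprintf("t(%s) = %s", format(df2), stat_s),
    F = sprintf(sample(c("F(%s, %s) = %s", "F(%s,%s) = %s"), 1),
                format(df1), format(df2), stat_s),
    r = sprintf("r(%s) = %s", format(df2), stat_s),
    chi2 = if (!is.na(n_rep)) {
      sprintf("chi2(%s, N = %s) = %s", format(df1), format(n_rep), stat_s)
    } else {
      sprintf("chi2(%s) = %s", format(df1), stat_s)
    },
    Z = sprintf("%s = %s", sample(c("Z", "z"), 1), stat_s)
  )
  p_part <- if (p$op == "ns") {
    sample(c("ns", "p = ns"), 1)
  } else {
    sprintf(sample(c("p %s %s", "p %s%s", "p%s %s"), 1),
            .op_sym[p$op], .fmt_p(p$pv, strip_zero = stats::runif(1) < 0.8))
  }
  plain <- paste0(stat_part, ", ", p_part)
  fam_html <- switch(family,
    chi2 = sub("^chi2", "&chi;<sup>2</sup>", stat_part),
    sub("^([tFrZz])", "<i>\\1</i>", stat_part)
  )
  html <- paste0(gsub("-", "&minus;", fam_html, fixed = TRUE), ", ",
                 sub("^p", "<i>p</i>", gsub("<", "&lt;", p_part, fixed = TRUE)))
  list(plain = plain, html = html)
}

.fillers <- c(
  "Participants completed the task in randomized order.",
  "Mean scores were 4.32 (SD = 1.21) and 3.87 (SD = 1.05).",
  "Descriptively, accuracy rose from 61.2 to 74.8 percent.",
  "The manipulation check confirmed the intended contrast.",
  "Reaction times were trimmed at 2.5 SD per cell.",
  "Internal consistency was adequate (alpha = .81).",
  "The sample comprised 120 undergraduates (M age = 19.4)."
)

.carriers <- c(
  "The main effect was reliable, %s.",
  "Group differences emerged, %s, in line with predictions.",
  "The interaction reached the criterion, %s.",
  "This association replicated, %s, across samples.",
  "The contrast was evaluated next, %s."
)

.ignorables <- function(k) {
  if (k == 0) return(character(0))
  vapply(seq_len(k), function(i) {
    kind <- sample(3, 1)
    if (kind == 1) {
      sprintf("F(%d, %d) = %.2f, MSE = %.2f, p < .02",
              sample(1:4, 1), sample(20:90, 1),
              stats::runif(1, 1, 8), stats::runif(1, 1, 12))
    } else if (kind == 2) {
      sprintf("F(1, %d) = %.1f and %.2f, p < .001 and p < .05, respectively",
              sample(10:40, 1), stats::runif(1, 5, 25), stats::runif(1, 3, 8))
    } else {
      sprintf("%.2f (%d, %d) .%02d", stats::runif(1, 1, 9),
              sample(1:4, 1), sample(20:90, 1), sample(1:9, 1))
    }
  }, character(1))
}

#' Generate one synthetic article with ground-truth labels
#'
#' Draws statistics and degrees of freedom, recomputes the true p-interval,
#' and prints either a compatible p (consistent), an incompatible p on the
#' same side of alpha (inconsistency), or an incompatible p crossing alpha
#' (gross inconsistency); infeasible draws are redrawn, so the emitted
#' ground truth is never mislabeled. Results are embedded in filler prose
#' with randomized APA-legal spacing; must-ignore strings and decoy decimal
#' numbers probe extractor precision.
#'
#' @param spec a [gen_spec()].
#' @param article_id id for the generated article.
#' @return a list: `article` (an `article_text`), `html` (the same content
#'   with simple markup: italics, entities, sup tags), `ground_truth`
#'   (data.frame: `article_id`, `result_index`, `family`, `df1`, `df2`,
#'   `stat_printed`, `p_op`, `p_printed`, `label`).
#' @examples
#' ga <- generate_article(gen_spec(n_results = 3, seed = 7))
#' ga$ground_truth$label
#' @export
generate_article <- function(spec, article_id = "synth001") {
  stopifnot(inherits(spec, "gen_spec"))
  set.seed(spec$seed)
  n <- spec$n_results
  n_inc <- if (!is.null(spec$n_inconsistent)) spec$n_inconsistent
           else round(spec$inconsistency_fraction * n)
  n_gross <- if (!is.null(spec$n_gross)) spec$n_gross
             else round(spec$gross_fraction * n)
  stopifnot(n_gross <= n_inc, n_inc <= n)
  labels <- c(rep("gross_inconsistency", n_gross),
              rep("inconsistency", n_inc - n_gross),
              rep("consistent", n - n_inc))
  labels <- sample(labels)

  rows <- vector("list", n)
  sent_plain <- character(n)
  sent_html <- character(n)
  for (i in seq_len(n)) {
    for (try in seq_len(200)) {
      fam <- sample(names(spec$families), 1, prob = spec$families)
      pars <- .draw_params(fam)
      pint <- recompute_p(list(family = fam, stat_value = pars$stat,
                               stat_decimals = 2L,
                               df1 = pars$df1, df2 = pars$df2))
      p <- .print_p(labels[i], pint$p_point, pint$p_low, pint$p_high,
                    fam %in% .symmetric, spec$one_tailed_mention)
      if (!is.null(p)) break
    }
    if (is.null(p)) {
      stop(sprintf("infeasible spec: could not realize label '%s'", labels[i]))
    }
    n_rep <- if (fam == "chi2" && stats::runif(1) < 0.4) {
      sample(30:500, 1)
    } else NA_real_
    stat_s <- .fmt_stat(fam, pars$stat)
    rend <- .render_result(fam, pars$df1, pars$df2, n_rep, stat_s, p)
    carrier <- sample(.carriers, 1)
    sent_plain[i] <- sprintf(carrier, rend$plain)
    sent_html[i] <- sprintf(carrier, rend$html)
    rows[[i]] <- data.frame(
      article_id = article_id, result_index = i, family = fam,
      df1 = pars$df1, df2 = pars$df2, stat_printed = stat_s,
      p_op = p$op, p_printed = p$pv, label = labels[i],
      stringsAsFactors = FALSE
    )
  }

  extra <- .ignorables(spec$include_ignorable)
  extra_carrier <- if (length(extra)) {
    sprintf("A further analysis gave %s.", extra)
  } else character(0)
  fill <- sample(.fillers, min(3, length(.fillers)))
  one_tailed <- if (spec$one_tailed_mention) {
    "All reported tests are one-tailed unless noted otherwise."
  } else character(0)
  between <- sample(.fillers, n, replace = TRUE)
  body_plain <- c(fill[1], one_tailed,
                  as.vector(rbind(sent_plain, between)),
                  extra_carrier, fill[2])
  body_html <- c(fill[1], one_tailed,
                 as.vector(rbind(sent_html, between)),
                 gsub("<", "&lt;", extra_carrier, fixed = TRUE), fill[2])
  text <- paste(body_plain, collapse = " ")
  html <- paste0("<html><body>",
                 paste0("<p>", body_html, "</p>", collapse = ""),
                 "</body></html>")
  gt <- if (n > 0) do.call(rbind, rows) else data.frame()
  list(article = new_article_text(article_id, normalize_text(text), "txt"),
       html = html,
       ground_truth = gt)
}

# spread `total` units over `n` slots as evenly as possible (constructed,
# not sampled)
.spread <- function(total, n) {
  base <- total %/% n
  extra <- total %% n
  c(rep(base + 1, extra), rep(base, n - extra))
}

#' Generate a synthetic corpus with exact seeded prevalences
#'
#' Articles are assigned evenly to calendar years; the seeded inconsistency
#' fraction follows a linear trend over years. Error counts per year are
#' constructed (rounded once per year, then spread over articles), so
#' corpus- and year-level prevalences match the seeded values exactly up to
#' that single rounding — running the pipeline and [yearly_trend()] on the
#' output recovers the seeded slope.
#'
#' @param n_articles total number of articles.
#' @param year_range `c(first, last)` calendar years.
#' @param inconsistency_fraction fraction of results seeded inconsistent in
#'   the first year (gross included).
#' @param gross_fraction fraction of results seeded gross (subset of
#'   inconsistent).
#' @param trend_per_year change in the inconsistency fraction per year
#'   (e.g. -0.005 is half a percentage point per year down).
#' @param results_per_article APA results embedded per article.
#' @param families,include_ignorable,one_tailed_mention passed to each
#'   article's [gen_spec()].
#' @param seed integer corpus seed.
#' @return a list: `articles` (list of `article_text`), `metadata`
#'   (data.frame `article_id`, `journal`, `year`), `ground_truth` (row-bound
#'   article ground truths).
#' @export
generate_corpus <- function(n_articles,
                            year_range = c(2000, 2000),
                            inconsistency_fraction = 0.10,
                            gross_fraction = 0.015,
                            trend_per_year = 0,
                            results_per_article = 10,
                            families = c(t = 0.3, F = 0.3, r = 0.15,
                                         chi2 = 0.15, Z = 0.1),
                            include_ignorable = 0,
                            one_tailed_mention = FALSE,
                            seed = 1L) {
  stopifnot(year_range[1] <= year_range[2], n_articles >= 1)
  set.seed(seed)
  years <- seq(year_range[1], year_range[2])
  ny <- length(years)
  per_year <- .spread(n_articles, ny)
  art_seeds <- sample.int(.Machine$integer.max - 1L, n_articles)
  journals <- c("JSYN-A", "JSYN-B", "JSYN-C", "JSYN-D")
  art_journal <- sample(journals, n_articles, replace = TRUE)

  # per-year error totals via cumulative rounding, so the corpus-level
  # count equals the rounded sum of the exact per-year targets (a single
  # per-year round() would let half-to-even ties drift the corpus total)
  fracs <- pmin(pmax(inconsistency_fraction +
                       trend_per_year * (years - years[1]), 0), 0.9)
  totals_y <- per_year * results_per_article
  inc_years <- diff(c(0, round(cumsum(fracs * totals_y))))
  gross_years <- pmin(diff(c(0, round(cumsum(gross_fraction * totals_y)))),
                      inc_years)

  articles <- vector("list", n_articles)
  meta <- vector("list", n_articles)
  gts <- vector("list", n_articles)
  k <- 0
  for (yi in seq_len(ny)) {
    nay <- per_year[yi]
    if (nay == 0) next
    inc_y <- inc_years[yi]
    gross_y <- gross_years[yi]
    inc_art <- .spread(inc_y, nay)
    gross_art <- integer(nay)
    g <- gross_y
    while (g > 0) {
      for (j in seq_len(nay)) {
        if (g > 0 && gross_art[j] < inc_art[j]) {
          gross_art[j] <- gross_art[j] + 1
          g <- g - 1
        }
      }
    }
    for (j in seq_len(nay)) {
      k <- k + 1
      id <- sprintf("art%05d", k)
      sp <- gen_spec(n_results = results_per_article,
                     families = families,
                     one_tailed_mention = one_tailed_mention,
                     include_ignorable = include_ignorable,
                     seed = art_seeds[k],
                     n_inconsistent = inc_art[j], n_gross = gross_art[j])
      ga <- generate_article(sp, article_id = id)
      articles[[k]] <- ga$article
      gts[[k]] <- ga$ground_truth
      meta[[k]] <- data.frame(article_id = id, journal = art_journal[k],
                              year = years[yi], stringsAsFactors = FALSE)
    }
  }
  list(articles = articles,
       metadata = do.call(rbind, meta),
       ground_truth = do.call(rbind, gts))
}

#' Write a generated corpus to disk
#'
#' One `.txt` file per article plus `metadata.csv` and `ground_truth.csv`.
#'
#' @param corpus a [generate_corpus()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_corpus <- function(corpus, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  for (a in corpus$articles) {
    writeLines(a$text, file.path(dir, paste0(a$article_id, ".txt")),
               useBytes = TRUE)
  }
  utils::write.csv(corpus$metadata, file.path(dir, "metadata.csv"),
                   row.names = FALSE)
  utils::write.csv(corpus$ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  invisible(dir)
}
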