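# Prevalence aggregation: per article, per group (journal/year), corpus
# totals, and linear trends.
#
# Two result-level summaries coexist on purpose: the pooled share of
# inconsistent results, and the unweighted mean over articles of the
# within-article percentage (the "(gross) inconsistency rate"). They differ
# whenever article sizes differ.

.classified <- function(records) {
  records[!is.na(records$label), , drop = FALSE]
}

#' Per-article consistency counts
#'
#' @param records classified records ([classify_results()] output) for one
#'   or more articles; rows with `NA` label (unclassifiable) are excluded.
#' @return a data.frame with one row per article: `article_id`,
#'   `n_results`, `n_inconsistent` (gross included), `n_gross`,
#'   `any_inconsistent`, `any_gross`, `pct_inconsistent`, `pct_gross`.
#'   Articles with zero classifiable results are absent.
#' @export
summarize_articles <- function(records) {
  records <- .classified(records)
  if (nrow(records) == 0) {
    stop("no classifiable records: per-article statistics are undefined")
  }
  sp <- split(records, records$article_id)
  out <- do.call(rbind, lapply(sp, function(r) {
    n <- nrow(r)
    ninc <- sum(r$label != "consistent")
    ngr <- sum(r$label == "gross_inconsistency")
    data.frame(article_id = r$article_id[1], n_results = n,
               n_inconsistent = ninc, n_gross = ngr,
               any_inconsistent = ninc > 0, any_gross = ngr > 0,
               pct_inconsistent = 100 * ninc / n,
               pct_gross = 100 * ngr / n,
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

.pct <- function(num, den) if (den == 0) NA_real_ else 100 * num / den

#' Corpus-level prevalence statistics
#'
#' Article-level percentages use article counts (denominator: articles with
#' at least one classifiable NHST result); result-level percentages pool
#' all records; the `(gross) inconsistency rate` is the *unweighted* mean
#' over articles of the within-article percentage, which is why it can
#' differ from the pooled share. Empty denominators yield `NA`, never 0.
#'
#' @param article_stats output of [summarize_articles()].
#' @param records the classified records the stats were computed from.
#' @return a one-row data.frame: `n_articles_with_nhst`, `n_results`,
#'   `pct_articles_any_inconsistent`, `pct_articles_any_gross`,
#'   `pct_results_inconsistent`, `pct_results_gross`, `inconsistency_rate`,
#'   `gross_rate`, `median_results_per_article`, `pct_reported_significant`,
#'   `pct_computed_significant`, `gross_rate_in_significant`,
#'   `gross_rate_in_nonsignificant`.
#' @export
summarize_corpus <- function(article_stats, records) {
  stopifnot(nrow(article_stats) >= 1)
  records <- .classified(records)
  n_art <- nrow(article_stats)
  n_res <- nrow(records)
  gross <- records$label == "gross_inconsistency"
  rs <- records$reported_significant
  data.frame(
    n_articles_with_nhst = n_art,
    n_results = n_res,
    pct_articles_any_inconsistent = .pct(sum(article_stats$any_inconsistent), n_art),
    pct_articles_any_gross = .pct(sum(article_stats$any_gross), n_art),
    pct_results_inconsistent = .pct(sum(records$label != "consistent"), n_res),
    pct_results_gross = .pct(sum(gross), n_res),
    inconsistency_rate = mean(article_stats$pct_inconsistent),
    gross_rate = mean(article_stats$pct_gross),
    median_results_per_article = stats::median(article_stats$n_results),
    pct_reported_significant = .pct(sum(rs, na.rm = TRUE), sum(!is.na(rs))),
    pct_computed_significant = .pct(sum(records$computed_significant), n_res),
    gross_rate_in_significant = .pct(sum(gross & !is.na(rs) & rs),
                                     sum(rs, na.rm = TRUE)),
    gross_rate_in_nonsignificant = .pct(sum(gross & !is.na(rs) & !rs),
                                        sum(!rs, na.rm = TRUE)),
    stringsAsFactors = FALSE
  )
}

#' Linear trend of a yearly percentage
#'
#' Ordinary least squares of a yearly percentage on calendar year, one
#' unweighted point per year, reporting the unstandardized slope `b`
#' (percentage points per year) and the variance explained `r2`. A
#' constant series has `b = 0` and, by convention, `r2 = 0` (no variance to
#' explain).
#'
#' @param year numeric vector of years (>= 2 distinct values).
#' @param pct numeric vector of percentages, same length.
#' @return a list of class `trend_stats`: `b`, `r2`, `n_years`.
#' @examples
#' yearly_trend(2000:2002, c(10, 12, 14))  # b = 2, r2 = 1
#' @export
yearly_trend <- function(year, pct) {
  keep <- !is.na(year) & !is.na(pct)
  year <- year[keep]; pct <- pct[keep]
  if (length(unique(year)) < 2) {
    stop(sprintf(
      "yearly trend needs >= 2 distinct years, got %d (series of length %d)",
      length(unique(year)), length(year)))
  }
  fit <- stats::lm(pct ~ year)
  b <- unname(stats::coef(fit)[2])
  r2 <- if (stats::var(pct) == 0) 0 else summary(fit)$r.squared
  structure(list(b = b, r2 = r2, n_years = length(unique(year))),
            class = "trend_stats")
}

#' @export
print.trend_stats <- function(x, ...) {
  cat(sprintf("<trend_stats> b = %.4g points/year, R^2 = %.3f (%d years)\n",
              x$b, x$r2, x$n_years))
  invisible(x)
}

#' Join article metadata and summarize per group
#'
#' @param records classified records.
#' @param metadata data.frame with `article_id` and grouping columns
#'   (typically `journal`, `year`), or `NULL`. Articles without a metadata
#'   row fall into group `"unknown"` (logged).
#' @param by character vector of metadata columns to group on.
#' @return a data.frame with one row per group: the grouping columns plus
#'   every [summarize_corpus()] field.
#' @export
summarize_groups <- function(records, metadata = NULL,
                             by = c("journal", "year")) {
  records <- .classified(records)
  if (is.null(metadata)) {
    metadata <- data.frame(article_id = unique(records$article_id),
                           group = "unknown", stringsAsFactors = FALSE)
    by <- "group"
  }
  by <- intersect(by, names(metadata))
  stopifnot(length(by) >= 1)
  idx <- match(records$article_id, metadata$article_id)
  if (anyNA(idx)) {
    miss <- unique(records$article_id[is.na(idx)])
    message(sprintf("reportcheck: %d article(s) without metadata -> group 'unknown': %s",
                    length(miss), paste(utils::head(miss, 5), collapse = ", ")))
  }
  g <- lapply(by, function(col) {
    v <- metadata[[col]][idx]
    v[is.na(idx)] <- "unknown"
    v
  })
  names(g) <- by
  key <- interaction(as.data.frame(g, stringsAsFactors = FALSE),
                     drop = TRUE, sep = "\r")
  out <- do.call(rbind, lapply(split(seq_len(nrow(records)), key), function(ix) {
    r <- records[ix, , drop = FALSE]
    cbind(as.data.frame(lapply(g, `[`, ix[1]), stringsAsFactors = FALSE),
          summarize_corpus(summarize_articles(r), r))
  }))
  rownames(out) <- NULL
  out
}
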