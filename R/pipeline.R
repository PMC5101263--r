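#' Run the full consistency check over a set of articles
#'
#' End-to-end pipeline: load and normalize each article, extract every
#' APA-formatted NHST result, recompute p-values with rounding-aware
#' semantics, apply the one-tailed rescue where the article text warrants
#' it, and classify every result.
#'
#' @param paths a directory or vector of `.html`/`.txt` files; alternatively
#'   pass pre-built `article_text` objects via `articles`.
#' @param articles optional list of `article_text` objects (used instead of
#'   `paths`).
#' @param format passed to [load_articles()].
#' @param policy a [consistency_policy()].
#' @return an object of class `reportcheck`: a list with `results` (the
#'   classified data.frame, one row per extracted result), `articles`
#'   (data.frame: `article_id`, `n_results`, `mentions_one_tailed`), and
#'   `policy`.
#' @examples
#' d <- tempfile(); dir.create(d)
#' writeLines("A t test gave t(28) = 2.0, p < .05.", file.path(d, "a1.txt"))
#' rc <- check_articles(d)
#' summary(rc)
#' @export
check_articles <- function(paths = NULL, articles = NULL,
                           format = c("auto", "html", "txt"),
                           policy = consistency_policy()) {
  format <- match.arg(format)
  if (is.null(articles)) {
    stopifnot(!is.null(paths))
    articles <- load_articles(paths, format = format)
  }
  res_list <- lapply(articles, extract_results)
  results <- do.call(rbind, res_list)
  mentions <- vapply(articles, function(a) {
    detect_one_tailed(a, policy$triggers)$mentions_one_tailed
  }, logical(1))
  ids <- vapply(articles, `[[`, character(1), "article_id")
  names(mentions) <- ids
  art_df <- data.frame(
    article_id = ids,
    n_results = vapply(res_list, nrow, integer(1)),
    mentions_one_tailed = unname(mentions),
    stringsAsFactors = FALSE
  )
  if (is.null(results) || nrow(results) == 0) {
    warning("no extractable APA results found in any input")
    results <- classify_results(extract_results(""))
  } else {
    results <- classify_results(results, one_tailed = mentions,
                                policy = policy)
  }
  structure(list(results = results, articles = art_df, policy = policy),
            class = "reportcheck")
}

#' @export
print.reportcheck <- function(x, ...) {
  r <- x$results[!is.na(x$results$label), , drop = FALSE]
  cat(sprintf("<reportcheck> %d article(s) scanned, %d with NHST results, %d result(s)\n",
              nrow(x$articles), sum(x$articles$n_results > 0), nrow(r)))
  if (nrow(r)) {
    tab <- table(factor(r$label, levels = c("consistent", "inconsistency",
                                            "gross_inconsistency")))
    cat(sprintf("  consistent: %d  inconsistent: %d (of which gross: %d)\n",
                tab[["consistent"]],
                tab[["inconsistency"]] + tab[["gross_inconsistency"]],
                tab[["gross_inconsistency"]]))
  }
  invisible(x)
}

#' @describeIn check_articles corpus-level summary statistics; returns the
#'   [summarize_corpus()] one-row data.frame invisibly.
#' @param object a `reportcheck` object.
#' @param ... unused.
#' @export
summary.reportcheck <- function(object, ...) {
  r <- object$results[!is.na(object$results$label), , drop = FALSE]
  if (nrow(r) == 0) {
    cat("no classifiable results\n")
    return(invisible(NULL))
  }
  cs <- summarize_corpus(summarize_articles(r), r)
  cat(sprintf("Articles with NHST results:        %d\n", cs$n_articles_with_nhst))
  cat(sprintf("NHST results:                      %d\n", cs$n_results))
  cat(sprintf("%% articles with an inconsistency:  %.1f\n",
              cs$pct_articles_any_inconsistent))
  cat(sprintf("%% articles with a gross error:     %.1f\n",
              cs$pct_articles_any_gross))
  cat(sprintf("%% results inconsistent (pooled):   %.1f\n",
              cs$pct_results_inconsistent))
  cat(sprintf("%% results gross (pooled):          %.1f\n",
              cs$pct_results_gross))
  cat(sprintf("inconsistency rate (per-article):  %.1f\n",
              cs$inconsistency_rate))
  cat(sprintf("gross rate (per-article):          %.1f\n", cs$gross_rate))
  invisible(cs)
}
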