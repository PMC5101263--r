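# Extraction grammar for completely and exactly APA-formatted NHST results:
#   FAMILY(df[, df | , N = n]) OP value, p OP value      (or the ns variant)
# Anything with interposed material (effect sizes, compound sentences,
# table fragments) deliberately fails to match.

# numbers: dfs may carry thousands separators ("1,024") and, for t/F,
# decimals (corrected dfs); p-values never carry separators
.re_df    <- "(?:\\d{1,3}(?:,\\d{3})+|\\d+)(?:\\.\\d+)?"
.re_int   <- "(?:\\d{1,3}(?:,\\d{3})+|\\d+)"
.re_val   <- "[-]?(?:\\d{1,3}(?:,\\d{3})+(?:\\.\\d+)?|\\d*\\.\\d+|\\d+)"
.re_p     <- "(?:\\d*\\.\\d+|\\d+(?:\\.\\d+)?)"

# ", p OP value" | ", ns" | ", p = ns"; bare "p > .05" stays an ordinary
# gt report, it is NOT folded into ns
.re_tail <- paste0(
  "\\s*,\\s*(?:(?<NSA>ns)(?![[:alnum:]])|p\\s*=\\s*(?<NSB>ns)(?![[:alnum:]])|",
  "p\\s*(?<POP>[<>=])\\s*(?<PVAL>", .re_p, ")(?!\\d))"
)

# family tokens: t/F/r case-sensitive, z/Z either case, chi2 is the
# canonical token produced by normalize_text(); a leading alphanumeric
# blocks the match so words like "result(" or "weight(" never fire
.re_family <- function(stat_part) {
  paste0("(?<![[:alnum:]_])", stat_part,
         "\\s*(?<SOP>[<>=])\\s*(?<SVAL>", .re_val, ")", .re_tail)
}

.patterns <- function() {
  c(
    t    = .re_family(paste0("t\\s*\\(\\s*(?<DF2>", .re_df, ")\\s*\\)")),
    F    = .re_family(paste0("F\\s*\\(\\s*(?<DF1>", .re_df, ")\\s*,\\s*(?<DF2>",
                             .re_df, ")\\s*\\)")),
    r    = .re_family(paste0("r\\s*\\(\\s*(?<DF2>", .re_df, ")\\s*\\)")),
    chi2 = .re_family(paste0("chi2\\s*\\(\\s*(?<DF1>\\d+)",
                             "(?:\\s*,\\s*N\\s*=\\s*(?<NREP>", .re_int,
                             "))?\\s*\\)")),
    Z    = .re_family("[Zz]")
  )
}

.strip_sep <- function(x) gsub(",", "", x, fixed = TRUE)

.n_decimals <- function(x) {
  ifelse(grepl(".", x, fixed = TRUE),
         nchar(sub(".*\\.", "", x)),
         0L)
}

.op_name <- c("<" = "lt", ">" = "gt", "=" = "eq")

# run one family's pattern, returning a raw data.frame of captures
.match_family <- function(text, family, pattern) {
  m <- gregexpr(pattern, text, perl = TRUE)[[1]]
  if (m[1] == -1) return(NULL)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  cs <- attr(m, "capture.start")
  cl <- attr(m, "capture.length")
  cap <- function(i, name) {
    if (!name %in% colnames(cs)) return(NA_character_)
    s <- cs[i, name]; l <- cl[i, name]
    if (s <= 0) NA_character_ else substr(text, s, s + l - 1)
  }
  do.call(rbind, lapply(seq_along(starts), function(i) {
    data.frame(
      family = family,
      df1_chr = cap(i, "DF1"),
      df2_chr = cap(i, "DF2"),
      n_chr = cap(i, "NREP"),
      stat_op_chr = cap(i, "SOP"),
      stat_chr = cap(i, "SVAL"),
      ns = !is.na(cap(i, "NSA")) || !is.na(cap(i, "NSB")),
      p_op_chr = cap(i, "POP"),
      p_chr = cap(i, "PVAL"),
      char_offset = starts[i],
      raw_span = substr(text, starts[i], starts[i] + lens[i] - 1),
      stringsAsFactors = FALSE
    )
  }))
}

#' Extract APA-formatted NHST results from normalized article text
#'
#' Finds every completely and exactly APA-formatted test result of the five
#' families (t, F, r, chi-squared, Z), with variable spacing, and parses it
#' into structured form. Results reported as nonsignificant (`, ns` or
#' `, p = ns`) are read too. Strings with interposed material — an effect
#' size between statistic and p-value, two results compounded into one
#' sentence, incomplete table fragments — do not match and are skipped.
#'
#' Matches with an invalid parse (negative F or chi-squared statistic,
#' reported p outside \[0, 1\]) are dropped with a message; the dropped
#' spans are returned in the `"dropped"` attribute.
#'
#' @param article an `article_text` object (or a character string, which is
#'   normalized first).
#' @return a data.frame with one row per result, in document order:
#'   `article_id`, `family`, `df1`, `df2`, `n_reported`, `stat_op`,
#'   `stat_value`, `stat_decimals`, `p_op` (`"lt"`, `"gt"`, `"eq"`, or
#'   `"ns"`), `p_value`, `p_decimals`, `raw_span`, `char_offset`.
#' @examples
#' extract_results("We found t(37) = -4.93, p < .001 in study 1.")
#' @export
extract_results <- function(article) {
  article <- as_article_text(article)
  text <- article$text
  pats <- .patterns()
  raw <- do.call(rbind, Map(function(fam, pat) .match_family(text, fam, pat),
                            names(pats), pats))
  empty <- data.frame(
    article_id = character(), family = character(), df1 = numeric(),
    df2 = numeric(), n_reported = numeric(), stat_op = character(),
    stat_value = numeric(), stat_decimals = integer(), p_op = character(),
    p_value = numeric(), p_decimals = integer(), raw_span = character(),
    char_offset = integer(), stringsAsFactors = FALSE
  )
  if (is.null(raw) || nrow(raw) == 0) {
    attr(empty, "dropped") <- empty[0, c("raw_span", "char_offset")]
    return(empty)
  }
  raw <- raw[order(raw$char_offset), , drop = FALSE]
  # non-overlapping, document order (family grammars are disjoint in
  # practice; guard anyway)
  keep <- rep(TRUE, nrow(raw))
  last_end <- 0
  for (i in seq_len(nrow(raw))) {
    end <- raw$char_offset[i] + nchar(raw$raw_span[i]) - 1
    if (raw$char_offset[i] <= last_end) keep[i] <- FALSE else last_end <- end
  }
  raw <- raw[keep, , drop = FALSE]

  out <- data.frame(
    article_id = article$article_id,
    family = raw$family,
    df1 = as.numeric(.strip_sep(raw$df1_chr)),
    df2 = as.numeric(.strip_sep(raw$df2_chr)),
    n_reported = as.numeric(.strip_sep(raw$n_chr)),
    stat_op = unname(.op_name[raw$stat_op_chr]),
    stat_value = as.numeric(.strip_sep(raw$stat_chr)),
    stat_decimals = as.integer(.n_decimals(.strip_sep(raw$stat_chr))),
    p_op = ifelse(raw$ns, "ns", unname(.op_name[raw$p_op_chr])),
    p_value = as.numeric(raw$p_chr),
    p_decimals = ifelse(raw$ns, NA_integer_,
                        as.integer(.n_decimals(raw$p_chr))),
    raw_span = raw$raw_span,
    char_offset = raw$char_offset,
    stringsAsFactors = FALSE
  )

  bad <- rep(FALSE, nrow(out))
  neg_upper <- out$family %in% c("F", "chi2") & out$stat_value < 0
  bad_p <- !is.na(out$p_value) & (out$p_value < 0 | out$p_value > 1)
  bad_df <- (!is.na(out$df1) & out$df1 <= 0) | (!is.na(out$df2) & out$df2 <= 0)
  bad <- neg_upper | bad_p | bad_df
  if (any(bad)) {
    for (sp in out$raw_span[bad]) {
      message(sprintf("reportcheck [%s]: dropped malformed result '%s'",
                      article$article_id, sp))
    }
  }
  dropped <- out[bad, c("raw_span", "char_offset"), drop = FALSE]
  out <- out[!bad, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "dropped") <- dropped
  out
}

#' Detect one-tailed-test language in an article
#'
#' Scans the whole article text, case-insensitively, for any of the trigger
#' phrases ("one-tailed", "one-sided", "directional" by default). The flag
#' is article-scoped: a single mention anywhere makes any otherwise
#' inconsistent symmetric-family result eligible for the one-tailed rescue.
#'
#' @param article an `article_text` object or character string.
#' @param triggers character vector of trigger phrases.
#' @return a list: `article_id`, `mentions_one_tailed`.
#' @export
detect_one_tailed <- function(article,
                              triggers = c("one-tailed", "one-sided",
                                           "directional")) {
  article <- as_article_text(article)
  hit <- any(vapply(triggers, function(tr) {
    grepl(tr, article$text, ignore.case = TRUE, fixed = FALSE)
  }, logical(1)))
  list(article_id = article$article_id, mentions_one_tailed = hit)
}
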