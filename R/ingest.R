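#' Normalize article text for extraction
#'
#' Maps typographic variants to the ASCII forms the extraction grammar
#' expects: Unicode minus to `-`, non-breaking/thin spaces to plain spaces,
#' fullwidth comparison signs to `<`, `>`, `=`, and the many renderings of
#' the chi-squared symbol (`χ²`, `χ^2^`, `chi-square`) to the
#' canonical token `chi2`. Whitespace runs (including line breaks) collapse
#' to single spaces so results split across lines still match.
#'
#' Normalization is idempotent and never alters digits, decimal points, or
#' parenthesis structure.
#'
#' @param x character vector.
#' @return character vector of the same length.
#' @export
normalize_text <- function(x) {
  x <- enc2utf8(as.character(x))
  x <- gsub("\u2212", "-", x)                       # unicode minus
  x <- gsub("[\u00a0\u2000-\u200b\u202f\u205f\u3000]", " ", x, perl = TRUE)
  x <- chartr("\uff1c\uff1e\uff1d", "<>=", x)       # fullwidth < > =
  # chi-squared token: Greek chi (either case) + superscript-two variants,
  # or the spelled-out form; "^2^" survives markdown-ish sup flattening
  x <- gsub("[\u03c7\u03a7]\\s*(?:\\^2\\^?|[2\u00b2])", "chi2", x, perl = TRUE)
  x <- gsub("chi[- ]squared?", "chi2", x, ignore.case = TRUE)
  x <- gsub("[ \t\r\n\f\v]+", " ", x)
  trimws(x)
}

new_article_text <- function(article_id, text, source_format) {
  structure(
    list(article_id = article_id, text = text, source_format = source_format),
    class = "article_text"
  )
}

#' @export
print.article_text <- function(x, ...) {
  cat(sprintf("<article_text> id=%s format=%s nchar=%d\n",
              x$article_id, x$source_format, nchar(x$text)))
  invisible(x)
}

# Read a file's bytes as UTF-8, falling back to latin-1 (logged) when the
# bytes are not valid UTF-8.
read_text_file <- function(path) {
  raw <- readBin(path, what = "raw", n = file.size(path))
  txt <- rawToChar(raw)
  if (validUTF8(txt)) {
    Encoding(txt) <- "UTF-8"
  } else {
    message(sprintf("reportcheck: '%s' is not valid UTF-8; assuming latin-1",
                    path))
    txt <- iconv(txt, from = "latin1", to = "UTF-8")
  }
  txt
}

html_to_text <- function(html) {
  # Block-level closers become line breaks before parsing so words in
  # adjacent paragraphs are not glued together; <sup>/<sub> are left inline
  # so "chi^2(" style markup flattens to a contiguous token.
  html <- gsub("(?i)<br\\s*/?>", "\n", html, perl = TRUE)
  html <- gsub("(?i)</(p|div|li|h[1-6]|tr|td|th|table|section|blockquote)>",
               "\n", html, perl = TRUE)
  doc <- xml2::read_html(html, encoding = "UTF-8")
  for (node in xml2::xml_find_all(doc, "//script|//style")) {
    xml2::xml_remove(node)
  }
  xml2::xml_text(doc)
}

#' Load one article file as normalized plain text
#'
#' HTML is parsed with \pkg{xml2}: tags are stripped, character entities
#' decoded, and superscript markup flattened so chi-squared results survive
#' as a contiguous token. Plain text is returned verbatim apart from
#' whitespace/Unicode normalization. PDF input is rejected: sign characters
#' in PDFs are frequently images and convert to garbage, so silent
#' mis-parsing is worse than an error.
#'
#' @param path path to a `.html`/`.htm` or `.txt` file.
#' @param format `"auto"` (by extension), `"html"`, or `"txt"`.
#' @param article_id identifier for the article; defaults to the file stem.
#' @return an `article_text` object: `article_id`, normalized `text`, and
#'   `source_format`.
#' @examples
#' f <- tempfile(fileext = ".txt")
#' writeLines("We found t(37) = -4.93, p < .001.", f)
#' load_article(f)
#' @export
load_article <- function(path, format = c("auto", "html", "txt"),
                         article_id = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) {
    stop(sprintf("cannot read article file '%s': no such file", path))
  }
  ext <- tolower(tools::file_ext(path))
  if (format == "auto") {
    format <- switch(ext,
      html = , htm = "html",
      txt = "txt",
      pdf = "pdf",
      stop(sprintf("cannot infer format of '%s' from extension '%s'",
                   path, ext))
    )
  }
  if (format == "pdf" || ext == "pdf") {
    stop(sprintf("unsupported format for '%s': PDF conversion is unreliable (comparison signs are often images); supply HTML or plain text", path))
  }
  raw_text <- read_text_file(path)
  text <- if (format == "html") html_to_text(raw_text) else raw_text
  if (is.null(article_id)) {
    article_id <- tools::file_path_sans_ext(basename(path))
  }
  new_article_text(article_id, normalize_text(text), format)
}

#' Load every article in a directory (or an explicit file list)
#'
#' A directory scan takes every `.html`, `.htm`, and `.txt` file; article
#' ids default to file stems and must be unique within one run.
#'
#' @param paths a directory or a character vector of file paths.
#' @param format passed to [load_article()].
#' @return a list of `article_text` objects.
#' @export
load_articles <- function(paths, format = c("auto", "html", "txt")) {
  format <- match.arg(format)
  if (length(paths) == 1 && dir.exists(paths)) {
    paths <- list.files(paths, pattern = "\\.(html?|txt)$",
                        full.names = TRUE, ignore.case = TRUE)
    paths <- sort(paths)
  }
  arts <- lapply(paths, load_article, format = format)
  ids <- vapply(arts, `[[`, character(1), "article_id")
  if (anyDuplicated(ids)) {
    stop(sprintf("duplicate article ids in run: %s",
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  arts
}

as_article_text <- function(x, article_id = "text") {
  if (inherits(x, "article_text")) return(x)
  new_article_text(article_id, normalize_text(x), "txt")
}
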