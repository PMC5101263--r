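Package: reportcheck
Title: Consistency Checking of Reported Statistical Test Results
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Extracts APA-formatted null-hypothesis significance test
    results (t, F, r, chi-squared, Z) from article full texts in HTML or
    plain text, recomputes the p-value implied by each test statistic and
    its degrees of freedom with rounding-aware interval semantics, labels
    every result as consistent, inconsistent, or grossly inconsistent
    (an error that flips the statistical conclusion at alpha = .05), and
    aggregates prevalence statistics per article, journal, and year,
    including linear trends. Includes a synthetic-article generator that
    seeds known error fractions so the whole pipeline can be validated
    end to end without access to any publisher corpus.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    stats,
    utils,
    xml2
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
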