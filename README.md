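# reportcheck

Roughly half of published psychology articles that report null-hypothesis
significance tests contain at least one p-value that disagrees with its own
test statistic and degrees of freedom. `reportcheck` finds such reporting
errors automatically: it extracts completely and exactly APA-formatted NHST
results from article full texts, recomputes every p-value from the printed
statistic, and classifies each result as consistent, an **inconsistency**,
or a **gross inconsistency** — an error that flips the statistical
conclusion at α = .05. It is aimed at meta-researchers auditing corpora,
editors and reviewers screening submissions, and authors checking their own
manuscripts.

## The check

An APA result string `t(df) = x, p OP v` is internally redundant: the
p-value is a deterministic function of the statistic. For the five
supported families the recomputed (two-tailed) p is

- *t*: `p = 2·P(T_df ≥ |x|)`
- *F*: `p = P(F_df1,df2 ≥ x)` (inherently upper-tail)
- *r*: converted via `t = r·√(df/(1−r²))`, df = N − 2, then as *t*
- *χ²*: `p = P(χ²_df ≥ x)` (inherently upper-tail)
- *Z*: `p = 2·P(|N(0,1)| ≥ |x|)`

Printed statistics are rounded, so a value printed as `2.0` stands for any
true value in the closed half-ULP interval [1.95, 2.05]. The recomputation
therefore yields a p-*interval*: for `t(28) = 2.0` the point value is .055
but the interval is [.0498, .0613], so `t(28) = 2.0, p < .05` is **not**
flagged — p = .0498 < .05 is attainable under rounding. A report is
inconsistent only when *no* value in the interval satisfies the printed
relation, and grossly inconsistent when, in addition, the reported and
recomputed significance at α = .05 disagree. Results reported as `ns`, the
"p = .05 counts as significant" convention, the "p = .000 is impossible"
rule, and an article-scoped one-tailed rescue (for t, r, Z when the text
mentions one-tailed/one-sided/directional testing) are all honoured.

## Worked example

```r
library(reportcheck)
rc <- check_text("The effect was clear, t(28) = 2.0, p < .05, while the
  covariate was weaker, F(2,56) = 1.203, p < .001.")
rc[, c("family", "raw_span", "computed_p", "computed_p_low",
       "computed_p_high", "label")]
#>   family                  raw_span computed_p computed_p_low computed_p_high
#> 1      t      t(28) = 2.0, p < .05 0.05528524     0.04983394      0.06125354
#> 2      F F(2,56) = 1.203, p < .001 0.30793267     0.30778508      0.30808033
#>                 label
#> 1          consistent
#> 2 gross_inconsistency
```

The t result survives because .0498 is attainable within statistic
rounding. The F result is the classic dropped-decimal typo (`1.203` for
`12.03`): the recomputed p ≈ .31 cannot be below .001, and the error flips
the conclusion, hence gross.

Corpus-scale use goes through files (`check_articles("dir/")`), and the
bundled generator produces ground-truth corpora:

```r
co  <- generate_corpus(50, c(2005, 2005), inconsistency_fraction = 0.10,
                       gross_fraction = 0.015, results_per_article = 10,
                       seed = 42)
out <- check_articles(articles = co$articles)
summary(out)
#> Articles with NHST results:        50
#> NHST results:                      500
#> % articles with an inconsistency:  100.0
#> % articles with a gross error:     16.0
#> % results inconsistent (pooled):   10.0
#> % results gross (pooled):          1.6
#> inconsistency rate (per-article):  10.0
#> gross rate (per-article):          1.6
```

Seeded prevalences are constructed, not sampled, so the pooled shares
reproduce the 10 % / 1.5–1.6 % targets exactly (the gross count rounds once
per corpus). `summarize_articles()`, `summarize_corpus()`,
`summarize_groups()`, and `yearly_trend()` aggregate per article, journal,
and year; `inst/cli/reportcheck` wraps scan/summarize/synth for the shell.

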