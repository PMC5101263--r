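---
title: "Rounding-aware consistency checking of reported NHST results"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Rounding-aware consistency checking of reported NHST results}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(reportcheck)
```

## The problem and the model

A null-hypothesis significance test reported in APA style —
`statistic(df) = value, p OP value` — contains redundant information: given
the family, the statistic, and its degrees of freedom, the p-value is a
deterministic tail probability. `reportcheck` exploits this redundancy to
audit reporting quality at corpus scale without any access to raw data.

The recomputation assumes every test is two-tailed, which is the dominant
convention and the only defensible default when the text does not say
otherwise. For the symmetric families (t, r, Z) the two-sided tail of
|statistic| is used; F and χ² are inherently upper-tail tests. A
correlation is converted by the exact test under bivariate normality,
`t = r√(df/(1−r²))` with the APA convention df = N − 2 — the only transform
consistent with a single parenthetical df. Tail probabilities are computed
in upper-tail form (`lower.tail = FALSE`), so tiny p-values suffer no
cancellation, and are clamped to the smallest positive double so the lower
interval endpoint is always strictly positive.

## Rounding semantics

A statistic printed with d decimals denotes an equivalence class: any true
value in the closed interval `value ± 0.5·10⁻ᵈ`. Mapping both endpoints
through the tail function yields a p-interval `[p_low, p_high]` that
brackets the point recomputation. The canonical boundary case:

```{r}
res <- extract_results("t(28) = 2.0, p < .05")
recompute_p(res[1, ])
```

The point p is .055, nominally above .05 — but p = .0498 is attainable for
a statistic that rounds to 2.0, so the report is *not* an inconsistency.
Both interval endpoints are treated as attainable (closed interval): a
boundary-equal value counts in favour of the author. For symmetric
families the interval is taken on |statistic|, so printed sign never
matters; an absolute bound crossing zero maps to p = 1, and an r-bound
reaching 1 maps to the positive floor.

## Compatibility and labels

A report is *compatible* when some q in the p-interval satisfies the
printed relation. Inequality bounds are taken literally (`p < .05` means
"some attainable q < .05"); only exact reports (`p = v`) additionally
receive their own half-ULP interval on the reported side, because an exact
print is itself a rounded number while an inequality expresses an exact
claim. `ns` is read as "q > α attainable". Two special rules: `p = .000`
is always incompatible (a p-value cannot be exactly zero), and `p = .05`
counts as a claim of significance, following observed reporting practice.

Labels partition classifiable records:

* **consistent** — compatible;
* **inconsistency** — incompatible;
* **gross inconsistency** — incompatible *and* the reported and computed
  significance at α disagree.

Computed significance uses the point recomputation with `p ≤ α`, mirroring
the reported-side `p = .05` convention; recomputed values within 1e-12 of
α are logged. A greater-than bound below α (`p > .01`) claims neither
significance nor nonsignificance; such records can be inconsistencies but
never gross, since gross requires an unambiguous claim. Records with
domain errors (|r| ≥ 1, nonpositive df) are excluded with a message —
never silently labeled.

When an article mentions one-tailed language anywhere ("one-tailed",
"one-sided", "directional"; case-insensitive, article-scoped), an initially
incompatible t, r, or Z result whose halved p-interval is compatible is
rescued to consistent. The rescue is monotone — it can only improve a
label — and never applies to F or χ², for which halving an upper-tail p
has no sampling-theory meaning.

## Extraction grammar

Only completely and exactly APA-formatted results are read: five families,
variable spacing, optional `N = n` inside χ² parentheses, `ns` variants
(`, ns` and `, p = ns`), thousands separators in dfs, decimal
(corrected) dfs for t and F, optional leading zeros in p and r. Deviating
strings — an effect size between statistic and p, compound sentences,
table fragments — are deliberately not matched; this mirrors the upstream
design choice that a conservative extractor with known blind spots beats a
permissive one with unknown false positives. Matches that parse to
impossible values (negative F or χ², p outside [0, 1]) are dropped and
logged. t/F/r tokens are case-sensitive (a capital `T(10) = ...` is some
other quantity); z is accepted in either case; the χ² symbol is normalized
from its many HTML renderings (`χ²`, `&chi;<sup>2</sup>`, `chi-square`) to
one canonical token before matching.

HTML input is parsed with xml2; PDF is rejected outright rather than
mis-parsed, because PDF-to-text conversion frequently replaces comparison
signs with images. Text normalization (unicode minus, exotic spaces,
fullwidth signs, whitespace collapse) is idempotent and never touches
digits or parentheses.

## Aggregation

Two result-level prevalences coexist deliberately: the pooled share of
inconsistent results, and the unweighted mean over articles of the
within-article percentage (the "(gross) inconsistency rate"). They answer
different questions — "how likely is a random p-value wrong?" versus "how
error-prone is a random article?" — and differ whenever article sizes
vary. Articles with zero extracted results are excluded from every
denominator; empty denominators yield `NA`, never 0, so "no data" and "no
errors" stay distinguishable. Yearly trends are plain OLS of a yearly
percentage on calendar year, one unweighted point per year, reporting the
unstandardized slope b and R²; a constant series has R² defined as 0.

## The synthetic-data generator

`generate_article()` draws a family, degrees of freedom, and a statistic
(two printed decimals), recomputes the true p-interval, and then *prints*
a p chosen to realize a target label: a compatible value (consistent), an
incompatible value on the same side of α (inconsistency), or an
incompatible value across α (gross). Seeded errors are placed at least
.001 beyond the compatible interval so no label depends on floating-point
hairlines; infeasible draws are redrawn, so emitted ground truth is never
mislabeled. Articles embed results in filler prose with randomized
APA-legal spacing, decoy decimals, optional must-ignore strings, and
optional one-tailed language (in which case seeded errors are also placed
outside the halved interval, so the rescue cannot undo them).

`generate_corpus()` assigns articles evenly to years and constructs error
counts: per-year totals come from cumulative rounding of the exact
targets (so the corpus total equals the rounded corpus target even when
per-year targets end in .5), then spread over articles by largest
remainder. Seeded prevalences are therefore exact by construction, and a
seeded linear trend in the inconsistency fraction is recovered by the
pipeline up to that one rounding per year.

Default study conditions used in the shipped validation: corpora of 200
articles with 10 results each, 10 % seeded inconsistent of which 15 %
gross (1.5 % of all results); trend recovery uses 20 years at 5 articles
per year and slope −0.5 percentage points per year across 10 seeds. These
sizes give exact constructed prevalences while keeping a full validation
run in tens of seconds.

What the generator does *not* emulate: real journal layout, tables,
reference lists, effect-size-rich reporting styles, multiple-testing
adjustments, or the correlation between article length and error rate.
Passing the round-trip test therefore shows the pipeline is internally
correct on conforming APA strings — it does not bound extraction recall on
real publisher HTML, which varies in markup idiosyncrasies the fixtures
only sample.

## Numerical choices and limitations

* Tail probabilities agree with an independent adaptive-quadrature oracle
  to 1e-10 across randomized draws of all five families (the test suite
  recomputes this on every run).
* Ties: `computed significant` uses `p ≤ α`; boundary interval endpoints
  are attainable; near-ties within 1e-12 of α are logged.
* p-values adjusted for multiple comparisons (Bonferroni and kin) are not
  modeled; an adjusted p larger than the recomputed one can be flagged
  spuriously. Corpus studies suggest such adjustments are rare, but on a
  manuscript that uses them the flags need manual review.
* The checker cannot tell *which* element of a flagged result is wrong
  (statistic, df, or p), and cannot distinguish core-hypothesis p-values
  from manipulation checks; prevalences are reporting-quality measures,
  not direct QRP measures.
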