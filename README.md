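# percentaudit

An audit pipeline for how percents are *presented* in biomedical abstracts.
Statistical software prints results to many decimal places, and authors often
copy them verbatim; readers then face either spurious precision ("83.12%")
or over-rounded values that hide real differences ("3%" for 263/8313).
`percentaudit` measures how often reported percents carry the recommended
number of decimal places, for meta-researchers and journal editors who want
to quantify (or automate feedback on) reporting quality.

## What it computes

For every percent mention `x%` in an abstract the pipeline records the
printed value *v*, the observed decimal places *d*, and the ideal decimal
places *d\*(v)* under a band operationalisation of Cole's presentation
guidelines:

| value band            | *d\** |
|-----------------------|------|
| v = 0                 | 1    |
| 0 < v < 0.001         | 4    |
| 0.001 ≤ v < 0.01      | 3    |
| 0.01 ≤ v < 0.1        | 2    |
| 0.1 ≤ v < 10          | 1    |
| 10 ≤ v ≤ 90           | 0    |
| 90 < v < 100          | 1    |
| v ≥ 100               | 0    |

(The one-decimal band just under 100 allows for natural upper bounds, e.g. a
test sensitivity of 99.9% rather than 100%.) Each mention is categorised by
the sign of *d − d\**: **too_few**, **just_right** or **too_many**.

Before classification, percents that merely *label* a statistical interval or
significance level are excluded: the common levels 80/90/95/99 printed as
integers near "confidence interval", "credible interval", "CI", "PI", the
transposed "IC", the observed typo "uncertainly interval", etc., and 1/5/10
near "significance" or "alpha level".

Category counts **n** = (n_few, n_right, n_many) are summarised with a
Dirichlet-multinomial model: with prior Dir(α) the posterior is
Dir(α + n), each category's marginal is Beta(α_i + n_i, Σ − α_i − n_i), and
equal-tailed 95% credible intervals come from Beta quantiles.

A sensitivity analysis re-runs the tally after dropping digit-preference
percents (integers that are multiples of 10, or 75 — typically thresholds or
pre-rounded values, not computed results) and/or percents in [90, 100].

A synthetic-corpus generator (`generate_corpus()`) plants percents with known
spans, values, decimal places, categories and interval-label flags, so the
whole pipeline is scored exactly in the tests without downloading anything.

## Worked example

```r
library(percentaudit)
txt <- normalize_text(
  "Mortality fell from 12% [95% CI 6-21%], to 3% [1-7%]. True retention was 242.73% after boiling.")
fl <- filter_labels(find_percents(txt), txt)
classify_percents(fl$kept)[, c("raw_token", "value", "decimals",
                               "ideal_decimals", "difference", "category")]
#>   raw_token  value decimals ideal_decimals difference   category
#> 1       12%  12.00        0              0          0 just_right
#> 3       21%  21.00        0              0          0 just_right
#> 4        3%   3.00        0              1         -1    too_few
#> 5        7%   7.00        0              1         -1    too_few
#> 6   242.73% 242.73        2              0          2   too_many
```

The "95%" of "95% CI" was excluded as an interval label; "3%" (a value under
10) should have carried one decimal place; "242.73%" (above 100) should have
been an integer.

A whole-corpus audit returns a `percent_audit` object:

```r
syn <- generate_corpus(generator_config(n_abstracts = 500), seed = 42)
fit <- audit_percents(syn$corpus)
fit
#> Percent decimal-place audit
#>   abstracts: 500 used (of 500 read)
#>   percents : 2575 extracted, 223 excluded as labels, 2352 analysed
#>   category split (% of analysed percents):
#>     too_few    14% (323)  [12 to 15%]
#>     just_right 60% (1,411)  [58 to 62%]
#>     too_many   26% (618)  [25 to 28%]
#>   abstracts with every percent ideal: 24% (118 of 500)
```

Each category line shows the share of analysed percents (formatted with its
own guideline-ideal decimals), the count, and the 95% credible interval.
`summary(fit)` adds per-journal tables; `write_audit_tables(fit, dir)` emits
the overall, per-journal, histogram-bin and per-mention CSVs. A thin CLI
wrapper with `audit` and `simulate` subcommands is in
`inst/cli/percentaudit.R`.

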