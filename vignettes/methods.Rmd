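---
title: "Auditing decimal places of percents: methods and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Auditing decimal places of percents: methods and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(percentaudit)
```

## The problem

Percents are the most text-minable statistic in abstracts: a number suffixed
with "%". How they are printed matters for readability — too many decimal
places tax the reader with spurious precision, too few can hide a difference.
`percentaudit` implements a rule-based audit of this presentation quality:
extraction, exclusion of interval labels, classification against a
decimal-place guideline, sensitivity filters, and Bayesian summaries of the
category proportions. This vignette records the method and every place where
the design was genuinely open, with the choice made and why.

## Extraction

Abstract text is first normalised: the "±" symbol is removed, no-break and
narrow spaces become plain spaces, Unicode minus and en/em dashes become
ASCII hyphens, the full-width "％" becomes "%", and a mid-dot between digits
("12·3", a Lancet-house-style decimal marker) becomes ".". The mid-dot rule
is an extension worth flagging: a corpus containing Lancet journals cannot
be parsed without it, and it is a pure character-level mapping.

A mention is then a number immediately followed by at most one space and
"%". The numeric part may carry comma thousands separators ("4,214.53%") or
omit the leading zero (".5%"). Deliberate non-matches, each a documented
choice:

* ranges — in "5 to 10%" or "5–10%" only "10%" is suffixed, so only 10 is
  extracted;
* signs and comparators — "−10%" and "<10%" record the value 10; the audit
  concerns presentation, not direction;
* numbers before the words "percent"/"per cent" (rare in this register, and
  out of reach of a suffix rule);
* scientific notation ("1e-4%"): a suffix regex would silently extract the
  mantissa's last digits, which is worse than nothing, so such matches are
  skipped with a warning;
* more than one space before "%" ("5  %") — "with or without a preceding
  space" is read as at most one.

Observed decimal places count printed digits after the point (trailing
zeros count: "50.0" has one). Significant figures use the printed-digit
convention: leading zeros insignificant, trailing zeros significant
(including those of bare integers, since we can only audit what is
printed).

## Interval and significance labels

"95%" in "95% CI 6–21%" names an interval's level; it is a label, not a
result, and must not be classified. A label rule pairs trigger values
(80, 90, 95, 99 for intervals; 1, 5, 10 for significance) with keyword
patterns and a character window. The vocabulary covers the seven interval
phrases plus the acronyms CI and PI, the transposed "IC", and the observed
typo "uncertainly interval"; the significance keywords are "significance",
"statistical significance" and "alpha level". Decisions where the original
description is silent:

* **Window**: at most 30 characters between token and keyword, on either
  side ("95% CI" and "CI 95%" both match). 30 characters spans the
  bracketed constructions seen in practice without reaching into
  neighbouring clauses too often. "range" is a common English word and only
  triggers within 5 characters. Both are config-exposed
  (`exclusion_rule()`).
* **Printed form**: triggers require zero decimal places. "95.0% CI" is
  retained — the enumerated labels are the printed common values, and a
  decimal-bearing level is anomalous enough to deserve a look rather than
  silent removal.
* Exclusion is per-mention, never per-sentence: "from 12% [95% CI 6-21%]"
  keeps 12 and 21 and removes only 95.

Windowed keyword matching has a known residual in both directions:
non-enumerated dialects ("95% fixed kernel density estimator") pass
through, and an unrelated trigger value that happens to sit within 30
characters of a keyword is removed. The tests exercise both behaviours.

## The guideline bands

The ideal decimal places d\*(v) follow the band table in the README. The
band edges are stated as "between" in prose guidelines, with no open/closed
convention, so the package fixes every band half-open and documents the
three ambiguous points: exactly 10 and exactly 90 take the integer rule
(fewer decimals when ambiguous), exactly 100 takes 0 (a trailing ".0" at
the bound conveys nothing). A percent of exactly 0 takes one decimal place
— "0.0%" signals a measured zero. Two clauses of the full guidelines are
deliberately not implemented: the
extra-precision allowance when compared percents differ by under 0.1
(affects very few abstracts and needs both percents at two decimals to
detect), and the no-decimals rule for denominators under 100 (sample sizes
are not extracted).

Classification is the sign of d − d\*: too_few, just_right, too_many.
Collapsing to three categories is justified by differences concentrating in
±1.

`format_percent()` inverts the rule: round half away from zero (manuscript
practice; on every table value checked it agrees with banker's rounding) to
d\*(v) digits, keeping trailing zeros. When rounding crosses a band edge
(9.97 → "10") the decimals are recomputed for the rounded value until
stable, so output always shows a value at its own ideal decimals.

## Sensitivity filters

Digit preference: integer-printed multiples of 10, and 75, are often
thresholds or pre-rounded values rather than computed results; a flag drops
them. The multiple-of-10 test is exact integer arithmetic on the printed
value — a value only qualifies when printed with zero decimals, so no float
modulo is ever taken. A second flag drops the closed band [90, 100], where
a natural upper bound at 100 may legitimately change the ideal decimals and
no automated judgement is possible; both endpoints sit against that bound,
hence closed. The two flags are independent and both off in the main
analysis. A published sensitivity tally of this kind can reflect either
exclusion or both, and the composition is rarely stated; the package
therefore exposes each separately rather than hard-wiring a combination.

## Dirichlet-multinomial summaries

With counts n over the three categories and prior Dir(α), the posterior is
Dir(α + n) and each category's marginal is Beta(α_i + n_i, Σ(α+n) − α_i −
n_i). Equal-tailed credible intervals come from Beta quantiles —
deterministic and optimisation-free, which is why equal-tailed was chosen
over HPD (the model statement names no interval type). The prior defaults
to the flat Dir(1,1,1), the minimal-information conventional choice (the
model statement names no prior); it is an argument, not a constant. A
Monte-Carlo mode (normalised Gamma draws) exists purely as an independent
cross-check of the quantile route and agrees within sampling error in the
tests. No clustering adjustment is made for multiple percents within one
abstract — intervals are therefore slightly anti-conservative, a stated
property of the audit design, not an accident.

Aggregation also reports the share of abstracts whose every retained
percent is just_right (abstracts with no retained percent leave the
denominator) and 1-point histogram bins over [0, 100], values above 100
counted separately.

## The synthetic corpus

`generate_corpus()` plants every percent token deliberately and records its
span, printed value, decimals, category and flags, making
precision/recall/accuracy computable exactly. What it emulates, with
defaults fixed once from the audited-corpus description:

* percents per abstract: 1 + NegBin(size = 1.2, μ = 3.5), grid-searched
  once (`scripts/calibrate_counts.R`) so the theoretical quartiles are
  exactly (2, 3, 6) — median 3, IQR 2–6;
* category probabilities (0.12, 0.55, 0.33) for mentions whose printed
  form is free to vary;
* digit-preference spikes at 10, 20, …, 90, 75, 1, 5, 95 at rate 0.19
  (the share of the full sample removed by the digit-preference
  exclusion); note 1, 5 and 95 are spikes the sensitivity filter
  deliberately does *not* remove;
* values above 100 at rate 0.005 (≈ the reported share);
* interval labels in five dialects (including "uncertainly interval" and
  the transposed "CI 95%") at rate 0.1 per mention — the source corpus
  reports no label rate, and one label per ten results is a realistic
  density for clinical abstracts;
* an adversarial mode injecting decoys ("P = 0.05", "5 mg", "Phase 3")
  that must never be extracted.

Mentions are drawn by rejection so that the *printed* token classifies
exactly as the planted category (rounding can cross a band edge, and a
category like too_few is impossible for an integer-band value, so the value
is redrawn until compatible). One deliberate unrealism: a label is never
attached to a sentence whose own result is an integer-printed 80/90/95/99,
because the label keyword would then sit inside that result's exclusion
window and the rules would — correctly, per their definition — remove a
planted result. Real abstracts do contain such collisions; the generator
avoids them so that the ground truth stays exact. Consequently, passing the
synthetic end-to-end tests shows the pipeline implements its rules
faithfully on clean, template-generated text; it does not show that the
rules themselves capture every dialect of real scientific prose (the
residual dialects noted in the exclusion section are the caveat there).

## Problem sizes and determinism

The test suite scores the pipeline on seeded corpora of 300–1,500 abstracts
(≈ 1,500–7,500 mentions), recovers generator category probabilities within
three binomial standard errors on 1,000 abstracts, checks interval coverage
with 500 multinomial replicates at n = 2,000, and validates the quantile
intervals against 10^6 posterior draws. All randomness flows through
explicit seeds; `generate_corpus()` restores the caller's RNG state.

## Known limitations

* Extraction is regex-based by design: percents in words, scientific
  notation, and non-suffix constructions are out of scope.
* Label exclusion is vocabulary-based; unseen dialects pass through, and a
  trigger value near an unrelated keyword can be over-excluded.
* Journal names are opaque grouping labels; no normalisation of journal
  strings is attempted.
* Credible intervals ignore within-abstract clustering.
* The guideline bands judge each percent in isolation; defensible
  presentations (small-n percents, deliberately consistent rounding within
  a sentence) are still counted against the guideline.
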