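---
title: "Disproportionality signal detection: models, conventions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Disproportionality signal detection: models, conventions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pvsignal)
```

## The problem

Spontaneous adverse-event (AE) reporting systems — FAERS, the WHO global
database behind VigiAccess, and their national counterparts — collect case
reports in which a reporter names one or more drugs and one or more adverse
events, coded as MedDRA preferred terms (PTs). Because there is no
denominator of exposed patients, safety signals are mined by
*disproportionality*: for a drug–event pair, the frequency with which the
event is reported for the drug is compared against its frequency among all
other reports, via the 2×2 table

|              | event | no event |
|--------------|-------|----------|
| target drug  | a     | b        |
| all others   | c     | d        |

`pvsignal` implements this pipeline end to end for report-level extracts in
the FAERS style — deduplication by case version, primary-suspect filtering
with product-name synonym lists, table construction, ROR/PRR screening,
PT→SOC aggregation, and demographic profiling — plus a synthetic report
generator whose planted associations have a *known* odds ratio, so that
every stage can be validated against ground truth.

## Statistics and screening rule

The two estimators are the classical frequentist disproportionality
measures:

- **Reporting odds ratio**: $ROR = \dfrac{a\,d}{b\,c}$, with a Wald interval
  on the log scale using $SE = \sqrt{1/a + 1/b + 1/c + 1/d}$.
- **Proportional reporting ratio**: $PRR = \dfrac{a/(a+b)}{c/(c+d)}$, with
  $SE = \sqrt{1/a - 1/(a+b) + 1/c - 1/(c+d)}$ on the log scale.
- **Chi-square**: the 2×2 Pearson statistic
  $\chi^2 = N(ad-bc)^2 / [(a+b)(c+d)(a+c)(b+d)]$; the Yates-corrected
  variant (the default, matching the classical PRR criterion convention)
  shrinks $|ad-bc|$ by $N/2$, clamped at zero.

A pair is a **signal** only when both criteria hold
(`screening_criteria()` defaults):

- PRR criterion: $a \ge 3$, $\chi^2 \ge 4$, $PRR \ge 2$;
- ROR criterion: $a \ge 3$ and the lower 95% confidence bound of the ROR
  strictly above 1.

`N` in the case-count gate is interpreted as `a`, the number of
co-occurrence reports — the standard reading of the criterion. Undefined
statistics (zero cells under the default policy) simply fail their
criterion; they never error. The confidence level, the four thresholds, the
Yates switch, and the zero-cell policy (`"undefined"` or Haldane–Anscombe
+0.5 with a `corrected` flag) are all parameters, because public tools
differ in these conventions and the source of a given published value is
rarely stated. With all cells positive, `ROR > 1 ⇔ PRR > 1 ⇔ ad > bc`, and
`ROR ≥ PRR ≥ 1` whenever `ROR > 1`; the test suite asserts both properties.

Ranking follows the two public conventions: signal league tables ranked by
the ROR lower confidence bound (signals only), and raw case-count rankings
in the style of VigiAccess (all pairs). Ties break by larger `a`, then
lexicographic PT.

## Counting conventions

- The counting unit is the **report** (distinct case), not the
  report–event row: a case mentioning a PT twice counts once in `a`.
- The comparator is the **full database**: all role/year-passing reports
  whose drug does not match the query.
- SOC-level "case numbers" are **record-level** sums over the SOC's PTs: a
  case reporting two PTs of one SOC counts twice. This matches the published
  aggregation, whose SOC totals exceed the number of unique cases. One
  published nintedanib SOC table prints its case-number and PT columns
  transposed; the bundled fixture stores the values under consistent column
  names.
- All printed percentages use **half-up rounding at two decimals**,
  implemented in exact integer arithmetic (`percentage()`); R's own
  `round()` rounds half to even and reproduces published tables incorrectly
  at `.005` boundaries.
- Deduplication keeps the **highest version per case id** (ties: last
  occurrence in input order), the standard FAERS curation rule; upstream
  retrieval tools deduplicate before export, so the rule is this package's
  documented choice rather than an assertion about any specific tool.
- Drug matching is exact after case-folding and trimming against an
  explicit synonym list, never substring matching: product names like
  "pirfenidone viatris" are listed as their own synonyms, and substring
  rules would create false matches.
- Sex/region/outcome values that are absent or unparseable become an
  explicit `unknown` category that stays in every denominator, because
  published cohort percentages are computed over all cases (missing age
  alone can exceed half the cohort). Receipt year is the only time field;
  date windows are applied at year precision.

## The synthetic generator

`generate_reports()` draws from a fully specified generative model so that
the implied odds ratio of every drug–event pair is available in closed form
(`implied_odds_ratio()`):

1. Each report is exposed to each configured drug independently
   (Bernoulli). Exactly one exposed drug is marked **primary suspect**,
   uniformly among the exposed; a report exposed to none draws its suspect
   from a pool of filler background products. Planted associations act
   through the suspect channel only.
2. Given the suspect, each PT enters the event set independently with
   probability `min(prob_cap, rho * background)`, where `rho` is the
   planted risk multiplier (`rho = 1` for unplanted pairs). Capping at 0.99
   emits a warning, never an error.
3. Demographics are drawn from configured marginals (sex, region, outcome,
   year trend); ages come from a two-component normal mixture truncated to
   [0, 130] with a missingness probability — the defaults emulate an
   elderly, male-skewed, Americas-dominated reporting population with an
   increasing year trend.
4. A configurable fraction of cases also emits a stale earlier version, so
   deduplication is exercised on realistic input.

For a single-drug world the implied odds ratio is
$\mathrm{odds}(\rho p)/\mathrm{odds}(p)$ — e.g. background 0.01 and
$\rho = 5$ give $(0.05/0.95)/(0.01/0.99) \approx 5.2105$. With several
configured drugs the comparator arm is the suspect-probability-weighted
mixture of the other drugs' (possibly planted) event rates and the filler
pool's background rate; suspect probabilities are computed by enumerating
the $2^K$ exposure subsets, which bounds the configured drug list at 20.

Two deliberate approximations, both documented because they bound what the
recovery tests show:

- Event sets must be non-empty (a spontaneous report without an event does
  not exist), so reports drawing an empty set are redrawn. This conditions
  the realized model on ≥1 event and perturbs inclusion probabilities by a
  factor of order the empty-set probability. The default study
  configurations (500 PTs at background 0.01, mean ≈5 events per report)
  keep that probability below 1%, far inside the ±15% recovery tolerance.
  Event sampling itself uses per-suspect-group binomial counts with
  uniformly sampled recipients, which is distributionally identical to
  independent per-report Bernoulli draws.
- Events are independent given the suspect (no event–event correlation),
  and exposures carry no demographic confounding. Real spontaneous data
  have neither property, so passing recovery tests validate the estimators
  and plumbing — not robustness to confounding, which crude
  disproportionality does not claim.

## Problem sizes and calibration checks

The package's own validation runs at the following sizes, chosen to make
binomial noise small relative to the tolerances asserted:

- **Parameter recovery**: n = 200,000 reports, one planted signal
  (ρ = 5, exposure 0.10, background 0.01, expected `a` ≈ 1,000); the
  empirical ROR must land within ±15% of the closed-form implied OR and the
  pair must be flagged. Typical observed error is 1–7%.
- **Null calibration**: n = 100,000 reports, five drugs, 500 PTs, all
  ρ = 1; fewer than 1% of the ~2,500 tested pairs may be flagged. The joint
  criteria are conservative; observed rates are at or near zero.
- **CI coverage**: 2,000 simulated tables at true OR = 3 (binomial rows
  with expected `a` = 30); the 95% Wald interval must cover 3 in
  93–97% of replicates.
- **Reference agreement**: on 1,000 random tables with cells up to 10⁵ the
  ROR point estimate matches the single-stratum Mantel–Haenszel common odds
  ratio (an algebraically identical but independently implemented route in
  base R) to better than 10⁻¹⁰ relative error, and the chi-square matches
  `stats::chisq.test` (same correction setting) to better than 10⁻⁸.

Full-database signal values published for real drugs (e.g. a lower
confidence bound of 52.21 for a pirfenidone–IPF pair) require the complete
FAERS 2015–2023 extract and are out of scope as numeric targets; the
planted-truth properties above are the substitute. What *is* reproduced
exactly are all published percentages derivable from printed counts: the
bundled SOC tables' percentage columns and the headline demographic ratios.

## Degenerate inputs and numerical notes

- All cell arithmetic is done in doubles; margin products up to 10²⁰ would
  overflow 32-bit integers.
- Zero cells: ROR undefined (default) or Haldane–Anscombe-corrected; PRR
  undefined when `a = 0` or `c = 0` (`b = 0` is legal); chi-square
  undefined on a zero margin. The `a ≥ 3` gate already excludes `a = 0`
  signals, so the zero policy only matters for `b`, `c`, `d`.
- An empty PT universe yields an empty table collection, not an error;
  all-zero tables are dropped by default (`restrict_observed`).
- Age bands are half-open `[low, high)` with the last band open-ended, so a
  65-year-old falls in the 65+ band; edges are configurable, defaults
  `[0,18), [18,45), [45,65), [65,75), [75,∞)`.
- `run_pipeline()` writes TSV artifacts and a JSON manifest with input
  hashes and the configuration echo, and contains nothing
  non-deterministic: re-running on identical inputs reproduces identical
  bytes.

## Known limitations

Crude (unstratified) disproportionality only — no age/sex adjustment, no
Bayesian shrinkage (IC, EBGM), no multiple-testing correction, and no
time-to-onset analysis; these are out of scope by design. The generator
does not model report narratives, drug–drug interaction structure, event
correlation, or secular coding drift. The PT→SOC mapping is single-level
many-to-one; the intermediate MedDRA levels (LLT/HLT/HLGT) and its
versioning are not represented.
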