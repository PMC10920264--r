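# pvsignal

Disproportionality signal detection for spontaneous adverse-event reports.

Spontaneous reporting databases (FAERS, the WHO database behind VigiAccess)
have no exposure denominator, so drug safety signals are mined by comparing
how often an event is reported *with* a drug against how often it is
reported with everything else. For each drug–event pair the 2×2 table

|              | event | no event |
|--------------|-------|----------|
| target drug  | a     | b        |
| all others   | c     | d        |

yields the **reporting odds ratio** `ROR = ad/bc` (log-scale Wald CI,
`SE = sqrt(1/a + 1/b + 1/c + 1/d)`) and the **proportional reporting
ratio** `PRR = [a/(a+b)] / [c/(c+d)]`. A pair is flagged as a signal only
when it passes *both* screening criteria:

* PRR criterion: `a >= 3`, `chi-square >= 4`, `PRR >= 2`;
* ROR criterion: `a >= 3` and the lower 95% CI bound of the ROR `> 1`.

`pvsignal` is aimed at pharmacoepidemiologists who work with FAERS-style
report-level extracts. It covers the whole path: reading long-format report
tables (configurable column dialects), case-version deduplication,
primary-suspect filtering with product-name synonym lists, 2×2 table
construction, ROR/PRR/chi-square screening, ranking by ROR lower bound or
by raw case count, MedDRA-style PT→SOC aggregation with the record-level
case-count convention, cohort demographics, and a synthetic report
generator with planted associations of **known, closed-form odds ratio**
for calibration and method validation.

## Worked example

Simulate a FAERS-like extract with one planted pirfenidone association
(risk multiplier 6 on a 2% background event), then detect it:

```r
library(pvsignal)

onto   <- generate_ontology(10, 10, seed = 3)          # 100 PTs over 10 SOCs
events <- setNames(rep(0.02, 100), names(onto))
cfg <- synthetic_config(
  n_reports = 20000,
  drugs = c(pirfenidone = 0.10),
  events = events,
  planted_signals = data.frame(drug = "pirfenidone", pt = "pt_0001", rho = 6),
  duplicate_fraction = 0.1,
  seed = 42)
sim <- generate_reports(cfg)

reports <- deduplicate(sim$reports)
parts   <- filter_reports(reports, drug_query("pirfenidone"))
stats   <- screen_tables(build_all_tables(parts$drug_reports,
                                          parts$background_reports))
rank_signals(stats, "by_ror_ci_low", top_k = 5)[,
  c("pt", "a", "ror", "ror_ci_low", "prr", "chi2", "is_signal")]
#>        pt   a   ror ror_ci_low   prr  chi2 is_signal
#> 1 pt_0001 299 6.677       5.72 5.856 743.1      TRUE

implied_odds_ratio(cfg, "pirfenidone", "pt_0001")
#> [1] 6.681818
```

The empirical ROR (6.677, lower bound 5.72) recovers the generator's
closed-form odds ratio (6.682), and the planted pair is the only signal.
SOC aggregation and demographics follow the published conventions
(record-level SOC counts; percentages half-up at 2 decimals over all
reports, unknowns retained):

```r
soc_summary(setNames(stats$a[stats$is_signal], stats$pt[stats$is_signal]), onto)
#>      soc case_number pt_count percentage
#> 1 soc_01         299        1        100

cohort_characteristics(parts$drug_reports)
#> <pv_cohort_summary> 2067 reports
#>   sex      top: male (1276, 61.73%)
#>   age      top: [65,75) (579, 28.01%)
#>   region   top: americas (1440, 69.67%)
#>   outcome  top: other (818, 39.57%)
#>   year     top: 2022 (521, 25.21%)
```

`run_pipeline()` runs the same flow from files (reports TSV, PT→SOC TSV,
YAML drug/criteria configs) and writes deterministic TSV artifacts plus a
JSON run manifest.

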