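# Bundled reference tables

Published aggregate summary counts for the antifibrotic drugs pirfenidone
and nintedanib, used by the test suite and the acceptance script to check
the percentage and SOC-aggregation conventions against printed values.

- `faers_*_soc.tsv`, `vigiaccess_*_soc.tsv` — SOC-level adverse-event case
  counts, distinct-PT counts, and the published percentage column, per drug
  and database. Columns are stored under consistent names
  (`soc, case_number, pt_count, percentage`); one published nintedanib FAERS
  table transposes its case-number and PT columns in print, and the file
  stores the values under their correct meanings (case numbers are the
  large column).
- `cohort_headline_counts.tsv` — headline demographic ratios (numerator,
  denominator, published percentage): over-65 share, hospitalization share,
  missing-age share.

All files are plain UTF-8 TSV with a header row.
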