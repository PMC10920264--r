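# Shared fixture builders. Everything is generated in code at test time.

# Report set built directly from field vectors; `events` is a list of
# character vectors.
make_rs <- function(case_id, events, drug_name = "drugX",
                    role = "primary_suspect", version = 0L, sex = "male",
                    age_years = NA_real_, region = "americas",
                    outcome = "other", year = 2020L, provenance = "test") {
  n <- length(case_id)
  df <- data.frame(case_id = case_id,
                   version = rep_len(version, n),
                   drug_name = rep_len(drug_name, n),
                   role = rep_len(role, n),
                   sex = rep_len(sex, n),
                   age_years = rep_len(age_years, n),
                   region = rep_len(region, n),
                   outcome = rep_len(outcome, n),
                   year = rep_len(year, n),
                   stringsAsFactors = FALSE)
  df$events <- events
  df <- df[, c("case_id", "version", "drug_name", "role", "events",
               "sex", "age_years", "region", "outcome", "year")]
  pvsignal:::new_report_set(df, provenance = provenance)
}

ct <- function(a, b, c, d, drug = "drugX", pt = "E") {
  data.frame(drug = drug, pt = pt, a = a, b = b, c = c, d = d,
             stringsAsFactors = FALSE)
}

# Small single-drug world: 500-PT ontology keeps the empty-event-set
# probability (and hence the >=1-event conditioning bias) below 1%.
std_events <- function(n_pt = 500, p = 0.01) {
  stats::setNames(rep(p, n_pt), sprintf("pt_%04d", seq_len(n_pt)))
}

recovery_config <- function(n = 200000, rho = 5, seed = 42) {
  ev <- std_events()
  synthetic_config(
    n_reports = n,
    drugs = c(drugX = 0.10),
    events = ev,
    planted_signals = data.frame(drug = "drugX", pt = names(ev)[1], rho = rho,
                                 stringsAsFactors = FALSE),
    duplicate_fraction = 0,
    seed = seed
  )
}

null_config <- function(n = 100000, seed = 11) {
  synthetic_config(
    n_reports = n,
    drugs = c(d1 = 0.05, d2 = 0.08, d3 = 0.12, d4 = 0.10, d5 = 0.06),
    events = std_events(),
    planted_signals = NULL,
    duplicate_fraction = 0,
    seed = seed
  )
}

# Independent reference odds ratio: single-stratum Mantel-Haenszel common OR
# (stats::mantelhaen.test on a duplicated stratum), which equals the sample
# cross-product ratio exactly.
ref_odds_ratio <- function(a, b, c, d) {
  arr <- array(as.numeric(c(a, c, b, d, a, c, b, d)), dim = c(2, 2, 2))
  unname(stats::mantelhaen.test(arr, exact = FALSE, correct = FALSE)$estimate)
}

ref_chi2 <- function(a, b, c, d, yates) {
  m <- matrix(as.numeric(c(a, c, b, d)), nrow = 2)
  unname(suppressWarnings(stats::chisq.test(m, correct = yates))$statistic)
}

extdata <- function(file) system.file("extdata", file, package = "pvsignal")

# Expand a SOC-level summary (case_number, pt_count) into a per-PT count
# vector whose soc_summary() aggregation reproduces it exactly: each SOC row
# becomes pt_count PTs, one carrying the remainder, the rest one case each.
expand_soc_counts <- function(soc_df) {
  pts <- character(); counts <- integer(); socs <- character()
  for (i in seq_len(nrow(soc_df))) {
    k <- soc_df$pt_count[i]
    cn <- soc_df$case_number[i]
    stopifnot(cn >= k)
    p <- sprintf("%s_pt%03d", gsub("[^A-Za-z]", "", soc_df$soc[i]), seq_len(k))
    pts <- c(pts, p)
    counts <- c(counts, c(cn - k + 1L, rep(1L, k - 1L)))
    socs <- c(socs, rep(soc_df$soc[i], k))
  }
  list(counts = stats::setNames(counts, pts), map = meddra_map(pts, socs))
}
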