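#' @importFrom stats rbinom rnorm runif setNames
NULL

default_demographics <- function() {
  list(
    sex = c(male = 0.60, female = 0.37, unknown = 0.03),
    region = c(americas = 0.70, europe = 0.15, asia = 0.08,
               oceania = 0.02, africa = 0.01, unknown = 0.04),
    outcome = c(hospitalization = 0.19, death = 0.10, life_threatening = 0.03,
                disability = 0.02, other = 0.40, unknown = 0.26),
    # receipt years with an increasing reporting trend
    years = setNames((1:8) / sum(1:8), 2015:2022)
  )
}

default_age_model <- function() {
  # elderly-skewed two-component mixture for an IPF-like population
  list(means = c(72, 55), sds = c(8, 12), weights = c(0.7, 0.3),
       missing = 0.20)
}

check_probs <- function(p, what, open = TRUE) {
  if (anyNA(p)) stop(what, " contains NA")
  if (open && (any(p <= 0) || any(p >= 1))) stop(what, " must be in (0, 1)")
  if (!open && (any(p < 0) || any(p > 1))) stop(what, " must be in [0, 1]")
  invisible(p)
}

#' Configuration for the synthetic report generator
#'
#' Defines a generative model for spontaneous reports: each report is exposed
#' to each configured drug independently (Bernoulli), exactly one exposed
#' drug is marked primary suspect (uniformly among the exposed; if none, the
#' suspect is drawn from a pool of `n_background_drugs` filler products);
#' each preferred term is then included in the report's event set
#' independently with its background probability, multiplied by the planted
#' risk multiplier `rho` when the suspect drug carries a planted signal for
#' that term (product capped at `prob_cap`). Demographics are drawn from
#' configured marginals; ages from a truncated normal mixture with a
#' missingness probability.
#'
#' @param n_reports Number of distinct cases to generate.
#' @param drugs Named numeric vector: drug name -> exposure probability in
#'   (0, 1).
#' @param events Named numeric vector: PT -> background inclusion probability
#'   in (0, 1).
#' @param planted_signals `NULL`, or data.frame with columns `drug`, `pt`,
#'   `rho` (risk multiplier, `rho >= 0`).
#' @param demographics List with named probability vectors `sex`, `region`,
#'   `outcome`, `years` (names are the category labels; `years` names are
#'   calendar years). Defaults emulate an elderly, Americas-dominated IPF
#'   reporting population.
#' @param age List `means`, `sds`, `weights` (normal mixture, truncated to
#'   `[0, 130]`) and `missing` (probability the age is unrecorded).
#' @param duplicate_fraction Probability a case also emits a stale
#'   earlier version (removed by [deduplicate()]).
#' @param n_background_drugs Size of the filler-drug pool for reports not
#'   exposed to any configured drug.
#' @param prob_cap Upper cap applied to `rho * background` probabilities.
#' @param seed Integer seed; generation is fully reproducible from it.
#' @return A `pv_synth_config`.
#' @export
synthetic_config <- function(n_reports,
                             drugs,
                             events,
                             planted_signals = NULL,
                             demographics = default_demographics(),
                             age = default_age_model(),
                             duplicate_fraction = 0.1,
                             n_background_drugs = 20L,
                             prob_cap = 0.99,
                             seed = 1L) {
  stopifnot(n_reports >= 1, n_background_drugs >= 1)
  if (is.null(names(drugs)) || is.null(names(events))) {
    stop("`drugs` and `events` must be named numeric vectors")
  }
  check_probs(drugs, "drug exposure probabilities")
  check_probs(events, "event background probabilities")
  if (anyDuplicated(names(drugs))) stop("duplicate drug names")
  if (anyDuplicated(names(events))) stop("duplicate event names")
  if (length(drugs) > 20L) {
    stop("at most 20 configured drugs supported (closed-form OR enumerates exposure sets)")
  }
  if (!is.null(planted_signals)) {
    stopifnot(is.data.frame(planted_signals),
              all(c("drug", "pt", "rho") %in% names(planted_signals)))
    if (!all(planted_signals$drug %in% names(drugs))) stop("planted signal for unknown drug")
    if (!all(planted_signals$pt %in% names(events))) stop("planted signal for unknown event")
    if (any(planted_signals$rho < 0)) stop("rho must be >= 0")
  }
  for (dim in c("sex", "region", "outcome", "years")) {
    p <- demographics[[dim]]
    if (is.null(p) || is.null(names(p))) stop("demographics$", dim, " must be named")
    check_probs(p, paste0("demographics$", dim), open = FALSE)
    if (abs(sum(p) - 1) > 1e-8) stop("demographics$", dim, " must sum to 1")
  }
  stopifnot(length(age$means) == length(age$sds),
            length(age$means) == length(age$weights),
            abs(sum(age$weights) - 1) < 1e-8,
            age$missing >= 0, age$missing <= 1,
            duplicate_fraction >= 0, duplicate_fraction < 1,
            prob_cap > 0, prob_cap < 1)
  structure(list(n_reports = as.integer(n_reports), drugs = drugs,
                 events = events, planted_signals = planted_signals,
                 demographics = demographics, age = age,
                 duplicate_fraction = duplicate_fraction,
                 n_background_drugs = as.integer(n_background_drugs),
                 prob_cap = prob_cap, seed = as.integer(seed)),
            class = "pv_synth_config")
}

#' @export
print.pv_synth_config <- function(x, ...) {
  cat(sprintf("<pv_synth_config> n=%d, %d drug(s), %d event PT(s), %d planted signal(s), seed=%d\n",
              x$n_reports, length(x$drugs), length(x$events),
              if (is.null(x$planted_signals)) 0L else nrow(x$planted_signals),
              x$seed))
  invisible(x)
}

#' Generate a synthetic PT-to-SOC ontology
#'
#' Builds a toy MedDRA-like mapping: `n_soc` system organ classes, each with
#' exactly `n_pt_per_soc` preferred terms. PT-to-SOC assignment is shuffled
#' under the seed so that PT indices carry no ordering information;
#' deterministic given the seed.
#'
#' @param n_soc Number of SOCs.
#' @param n_pt_per_soc PTs per SOC.
#' @param seed Integer seed.
#' @return A `pv_meddra_map` of size `n_soc * n_pt_per_soc`.
#' @export
generate_ontology <- function(n_soc, n_pt_per_soc, seed = 1L) {
  if (n_soc < 1 || n_pt_per_soc < 1) stop("sizes must be positive")
  n_pt <- n_soc * n_pt_per_soc
  pts <- sprintf("pt_%04d", seq_len(n_pt))
  socs <- sprintf("soc_%02d", seq_len(n_soc))
  with_seed(seed, {
    assignment <- sample(rep(socs, each = n_pt_per_soc))
  })
  meddra_map(pts, assignment)
}

# Per-suspect-group event-inclusion probabilities: matrix [group x PT].
# Groups are the configured drugs plus one "background" filler group.
suspect_event_probs <- function(cfg) {
  drugs <- names(cfg$drugs)
  pts <- names(cfg$events)
  probs <- matrix(rep(cfg$events, times = length(drugs) + 1L),
                  nrow = length(drugs) + 1L, byrow = TRUE,
                  dimnames = list(c(drugs, ".background"), pts))
  ps <- cfg$planted_signals
  capped <- 0L
  if (!is.null(ps) && nrow(ps)) {
    for (i in seq_len(nrow(ps))) {
      p <- cfg$events[[ps$pt[i]]] * ps$rho[i]
      if (p > cfg$prob_cap) {
        p <- cfg$prob_cap
        capped <- capped + 1L
      }
      probs[ps$drug[i], ps$pt[i]] <- p
    }
  }
  if (capped > 0L) {
    warning(sprintf("%d planted probability value(s) capped at %.2f", capped, cfg$prob_cap))
  }
  probs
}

# P(primary suspect = each configured drug) and P(suspect is a filler drug),
# by enumeration of the 2^K exposure subsets (suspect uniform among exposed).
suspect_probs <- function(cfg) {
  q <- cfg$drugs
  k <- length(q)
  p_drug <- numeric(k)
  p_empty <- prod(1 - q)
  if (k > 0L) {
    subsets <- expand.grid(rep(list(c(FALSE, TRUE)), k))
    for (s in seq_len(nrow(subsets))) {
      inc <- as.logical(subsets[s, ])
      if (!any(inc)) next
      pr <- prod(ifelse(inc, q, 1 - q))
      p_drug[inc] <- p_drug[inc] + pr / sum(inc)
    }
  }
  list(drug = setNames(p_drug, names(q)), filler = p_empty)
}

#' Closed-form implied odds ratio of the generative model
#'
#' The odds ratio of event occurrence comparing reports whose primary
#' suspect is `drug` against all other reports, computed analytically from
#' the configuration: the exposed arm reports the event with probability
#' `min(prob_cap, rho * p)`; the comparator arm mixes the other configured
#' drugs (with their own planted multipliers, if any) and the filler pool at
#' the background probability. Equals 1 whenever `rho = 1` and no other drug
#' carries a planted signal for the event.
#'
#' @param cfg A [synthetic_config()].
#' @param drug Configured drug name.
#' @param event Configured PT name.
#' @return Positive scalar odds ratio.
#' @export
implied_odds_ratio <- function(cfg, drug, event) {
  stopifnot(inherits(cfg, "pv_synth_config"))
  if (!drug %in% names(cfg$drugs)) stop("unknown drug: ", drug)
  if (!event %in% names(cfg$events)) stop("unknown event: ", event)
  probs <- suppressWarnings(suspect_event_probs(cfg))
  sp <- suspect_probs(cfg)
  p_target <- probs[drug, event]
  others <- setdiff(names(cfg$drugs), drug)
  num <- sum(sp$drug[others] * probs[others, event]) + sp$filler * cfg$events[[event]]
  p_other <- num / (1 - sp$drug[[drug]])
  (p_target / (1 - p_target)) / (p_other / (1 - p_other))
}

sample_truncated_mixture <- function(n, age) {
  comp <- sample.int(length(age$weights), n, replace = TRUE, prob = age$weights)
  x <- rnorm(n, mean = age$means[comp], sd = age$sds[comp])
  bad <- which(x < 0 | x > 130)
  guard <- 0L
  while (length(bad) && guard < 100L) {
    comp_b <- sample.int(length(age$weights), length(bad), replace = TRUE,
                         prob = age$weights)
    x[bad] <- rnorm(length(bad), mean = age$means[comp_b], sd = age$sds[comp_b])
    bad <- bad[x[bad] < 0 | x[bad] > 130]
    guard <- guard + 1L
  }
  x[x < 0] <- 0; x[x > 130] <- 130
  round(x, 1)
}

# Draw event sets for `n` reports in suspect group `gi` (row of `probs`):
# grouped binomial counts per PT, recipients sampled uniformly, which is
# distributionally identical to independent Bernoulli per (report, PT).
draw_group_events <- function(n, p_row, pts) {
  counts <- rbinom(length(p_row), size = n, prob = p_row)
  nz <- which(counts > 0L)
  if (!length(nz)) {
    return(rep.int(list(character()), n))
  }
  report_idx <- unlist(lapply(nz, function(j) sample.int(n, counts[j])),
                       use.names = FALSE)
  pt_idx <- rep.int(nz, counts[nz])
  ev <- split(pts[pt_idx], factor(report_idx, levels = seq_len(n)))
  unname(ev)
}

#' Generate a synthetic spontaneous-report dataset with known ground truth
#'
#' Draws `n_reports` distinct cases from the generative model described in
#' [synthetic_config()], plus stale duplicate versions per
#' `duplicate_fraction`. Reports that draw an empty event set are redrawn
#' (every report carries at least one PT); the resulting conditioning
#' perturbs event probabilities by a factor of order the empty-set
#' probability, negligible for the default configurations.
#'
#' @param cfg A [synthetic_config()].
#' @return A list: `reports` (a `pv_report_set`, raw, including duplicate
#'   versions) and `truth` (data.frame `drug, pt, rho, implied_or` covering
#'   every configured drug-PT pair).
#' @export
generate_reports <- function(cfg) {
  stopifnot(inherits(cfg, "pv_synth_config"))
  n <- cfg$n_reports
  probs <- suspect_event_probs(cfg)
  pts <- colnames(probs)
  drugs <- names(cfg$drugs)
  k <- length(drugs)

  with_seed(cfg$seed, {
    # exposures and primary suspect
    expo <- matrix(runif(n * k) < rep(cfg$drugs, each = n), nrow = n)
    n_expo <- rowSums(expo)
    suspect <- integer(n) # 0 = filler pool
    multi <- which(n_expo > 0L)
    if (length(multi)) {
      if (k == 1L) {
        suspect[multi] <- 1L
      } else {
        pick <- ceiling(runif(length(multi)) * n_expo[multi])
        csum <- t(apply(expo[multi, , drop = FALSE], 1L, cumsum))
        suspect[multi] <- max.col(csum >= pick, ties.method = "first")
      }
    }
    filler_names <- sprintf("background_drug_%02d", seq_len(cfg$n_background_drugs))
    drug_name <- character(n)
    drug_name[suspect > 0L] <- drugs[suspect[suspect > 0L]]
    n_fill <- sum(suspect == 0L)
    drug_name[suspect == 0L] <- filler_names[
      sample.int(cfg$n_background_drugs, n_fill, replace = TRUE)]

    # events: grouped binomial per suspect group, redraw empty reports
    events <- vector("list", n)
    group <- ifelse(suspect == 0L, k + 1L, suspect) # row index into probs
    for (gi in seq_len(k + 1L)) {
      members <- which(group == gi)
      if (!length(members)) next
      ev <- draw_group_events(length(members), probs[gi, ], pts)
      guard <- 0L
      repeat {
        empty <- which(lengths(ev) == 0L)
        if (!length(empty) || guard >= 50L) break
        ev[empty] <- draw_group_events(length(empty), probs[gi, ], pts)
        guard <- guard + 1L
      }
      still <- which(lengths(ev) == 0L)
      if (length(still)) { # pathological configs: force one PT, scaled draw
        ev[still] <- as.list(sample(pts, length(still), replace = TRUE,
                                    prob = probs[gi, ]))
      }
      events[members] <- ev
    }

    # demographics
    dm <- cfg$demographics
    draw_cat <- function(p) names(p)[sample.int(length(p), n, replace = TRUE, prob = p)]
    sex <- draw_cat(dm$sex)
    region <- draw_cat(dm$region)
    outcome <- draw_cat(dm$outcome)
    year <- as.integer(draw_cat(dm$years))
    age_years <- sample_truncated_mixture(n, cfg$age)
    age_years[runif(n) < cfg$age$missing] <- NA_real_

    # stale duplicate versions
    dup <- runif(n) < cfg$duplicate_fraction
    version <- ifelse(dup, 1L, 0L)
  })

  case_id <- sprintf("case_%07d", seq_len(n))
  final <- data.frame(case_id = case_id, version = version,
                      drug_name = drug_name, role = "primary_suspect",
                      sex = sex, age_years = age_years, region = region,
                      outcome = outcome, year = year,
                      stringsAsFactors = FALSE)
  final$events <- events
  if (any(dup)) {
    stale <- final[dup, , drop = FALSE]
    stale$version <- 0L
    raw <- rbind(stale, final)
    raw <- raw[order(match(raw$case_id, case_id), raw$version), , drop = FALSE]
  } else {
    raw <- final
  }
  raw <- raw[, c("case_id", "version", "drug_name", "role", "events",
                 "sex", "age_years", "region", "outcome", "year")]
  rownames(raw) <- NULL

  truth <- expand.grid(drug = drugs, pt = pts, stringsAsFactors = FALSE)
  truth$rho <- 1
  ps <- cfg$planted_signals
  if (!is.null(ps) && nrow(ps)) {
    idx <- match(paste(ps$drug, ps$pt), paste(truth$drug, truth$pt))
    truth$rho[idx] <- ps$rho
  }
  truth$implied_or <- vapply(seq_len(nrow(truth)), function(i) {
    implied_odds_ratio(cfg, truth$drug[i], truth$pt[i])
  }, numeric(1))

  list(reports = new_report_set(raw,
                                provenance = sprintf("synthetic(seed=%d)", cfg$seed)),
       truth = truth)
}

#' Write a generator truth table to TSV
#'
#' @param truth The `truth` data.frame from [generate_reports()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_table <- function(truth, path) {
  data.table::fwrite(truth, path, sep = "\t", quote = FALSE)
  invisible(path)
}
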