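#' @importFrom data.table fread fwrite data.table as.data.table setDF :=
#' @importFrom stats ave
NULL

# Canonical factor levels for categorical report fields.
ROLE_LEVELS <- c("primary_suspect", "secondary_suspect", "concomitant", "interacting")
SEX_LEVELS <- c("male", "female", "unknown")
REGION_LEVELS <- c("americas", "europe", "asia", "oceania", "africa", "unknown")
OUTCOME_LEVELS <- c("death", "life_threatening", "hospitalization", "disability",
                    "other", "unknown")

# Lenient code maps used by the reader (FAERS-style role codes etc.).
ROLE_CODES <- c(
  ps = "primary_suspect", primary_suspect = "primary_suspect",
  primary = "primary_suspect",
  ss = "secondary_suspect", secondary_suspect = "secondary_suspect",
  secondary = "secondary_suspect",
  c = "concomitant", concomitant = "concomitant",
  i = "interacting", interacting = "interacting"
)
SEX_CODES <- c(m = "male", male = "male", f = "female", female = "female",
               unknown = "unknown", u = "unknown")

#' Column dialect for report files
#'
#' Spontaneous-report extracts differ in delimiter and column naming (FAERS
#' quarterly files, OpenVigil exports, this package's own writer). A dialect
#' declares the delimiter and the mapping from canonical field names to the
#' column headers found in the file.
#'
#' @param name Label for the dialect.
#' @param delim Field delimiter (default tab; use "," for CSV).
#' @param columns Named character vector mapping the canonical fields
#'   `case_id, version, drug_name, role, event, sex, age, region, outcome,
#'   year` to the file's column names. Fields omitted from the file may be
#'   dropped from the mapping only if optional (`version, sex, age, region,
#'   outcome`).
#' @return An object of class `pv_dialect`.
#' @export
report_dialect <- function(name = "pvsignal",
                           delim = "\t",
                           columns = c(case_id = "case_id", version = "version",
                                       drug_name = "drug_name", role = "role",
                                       event = "event_pt", sex = "sex",
                                       age = "age_years", region = "region",
                                       outcome = "outcome", year = "year")) {
  mandatory <- c("case_id", "drug_name", "role", "event", "year")
  missing_mand <- setdiff(mandatory, names(columns))
  if (length(missing_mand)) {
    stop("dialect must map mandatory fields: ", paste(missing_mand, collapse = ", "))
  }
  structure(list(name = name, delim = delim, columns = columns),
            class = "pv_dialect")
}

#' @export
print.pv_dialect <- function(x, ...) {
  cat("<pv_dialect>", x$name, "delim:",
      if (x$delim == "\t") "TAB" else x$delim, "\n")
  invisible(x)
}

# Construct a report set from a case-level data.frame.
# `reports` columns: case_id, version, drug_name, role, events (list of
# character PT sets), sex, age_years, region, outcome, year.
new_report_set <- function(reports, provenance = "",
                           log = list(rows_read = nrow(reports),
                                      rows_rejected = 0L,
                                      fields_coerced = 0L)) {
  stopifnot(is.data.frame(reports))
  structure(list(reports = reports, provenance = provenance, log = log),
            class = "pv_report_set")
}

#' Number of reports in a report set
#' @param rs A `pv_report_set`.
#' @return Integer count of reports (case records, before/after deduplication
#'   depending on the set).
#' @export
n_reports <- function(rs) {
  stopifnot(inherits(rs, "pv_report_set"))
  nrow(rs$reports)
}

#' Run log of a report set
#'
#' Readers record how many raw rows they saw, how many were rejected for
#' unparseable mandatory fields, and how many optional fields were coerced to
#' unknown/missing.
#'
#' @param rs A `pv_report_set`.
#' @return A list with `rows_read`, `rows_rejected`, `fields_coerced`.
#' @export
run_log <- function(rs) {
  stopifnot(inherits(rs, "pv_report_set"))
  rs$log
}

#' @export
print.pv_report_set <- function(x, ...) {
  cat(sprintf("<pv_report_set> %d reports (%d distinct cases)\n",
              nrow(x$reports), length(unique(x$reports$case_id))))
  if (nzchar(x$provenance)) cat("  provenance:", x$provenance, "\n")
  if (x$log$rows_rejected > 0L) {
    cat("  rejected rows:", x$log$rows_rejected, "\n")
  }
  invisible(x)
}

#' Read spontaneous reports from a delimited file
#'
#' Parses a long-format report table (one row per report-drug-event record)
#' and regroups rows sharing `case_id` and `version` into one report with an
#' event set. Parsing is lenient for optional fields: an unparseable sex,
#' age, region or outcome becomes unknown/missing and is counted in the run
#' log. Rows with unparseable mandatory fields (`case_id`, `drug_name`,
#' `role`, `event`, `year`) are rejected and counted.
#'
#' @param path Path to the file.
#' @param dialect A [report_dialect()] describing delimiter and columns.
#' @return A `pv_report_set`; inspect [run_log()] for rejection counts.
#' @export
read_reports <- function(path, dialect = report_dialect()) {
  if (!file.exists(path)) stop("report file not found: ", path)
  cols <- dialect$columns
  raw <- data.table::fread(path, sep = dialect$delim, header = TRUE,
                           colClasses = "character", na.strings = c("", "NA"))
  missing_cols <- setdiff(unname(cols), names(raw))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "))
  }
  if (nrow(raw) == 0L) {
    reports <- data.frame(case_id = character(), version = integer(),
                          drug_name = character(), role = character(),
                          sex = character(), age_years = numeric(),
                          region = character(), outcome = character(),
                          year = integer())
    reports$events <- list()
    return(new_report_set(reports, provenance = path,
                          log = list(rows_read = 0L, rows_rejected = 0L,
                                     fields_coerced = 0L)))
  }

  g <- function(field) {
    if (field %in% names(cols) && cols[[field]] %in% names(raw)) {
      raw[[cols[[field]]]]
    } else {
      rep(NA_character_, nrow(raw))
    }
  }

  case_id <- trimws(g("case_id"))
  drug_name <- trimws(g("drug_name"))
  role_raw <- tolower(trimws(g("role")))
  role <- unname(ROLE_CODES[role_raw])
  event <- trimws(g("event"))
  year <- suppressWarnings(as.integer(g("year")))

  version_raw <- g("version")
  version <- suppressWarnings(as.integer(version_raw))
  version_coerced <- sum(is.na(version) & !is.na(version_raw))
  version[is.na(version)] <- 0L

  sex_raw <- g("sex")
  sex <- unname(SEX_CODES[tolower(trimws(sex_raw))])
  sex_coerced <- sum(is.na(sex) & !is.na(sex_raw))
  sex[is.na(sex)] <- "unknown"

  age_raw <- g("age")
  age <- suppressWarnings(as.numeric(age_raw))
  bad_age <- (!is.na(age) & (age < 0 | age > 130)) | (is.na(age) & !is.na(age_raw))
  age_coerced <- sum(bad_age)
  age[!is.na(age) & (age < 0 | age > 130)] <- NA_real_

  region_raw <- tolower(trimws(g("region")))
  region <- ifelse(region_raw %in% REGION_LEVELS, region_raw, NA_character_)
  region_coerced <- sum(is.na(region) & !is.na(g("region")))
  region[is.na(region)] <- "unknown"

  outcome_raw <- tolower(trimws(g("outcome")))
  outcome <- ifelse(outcome_raw %in% OUTCOME_LEVELS, outcome_raw, NA_character_)
  outcome_coerced <- sum(is.na(outcome) & !is.na(g("outcome")))
  outcome[is.na(outcome)] <- "unknown"

  ok <- !is.na(case_id) & nzchar(case_id) &
    !is.na(drug_name) & nzchar(drug_name) &
    !is.na(role) & !is.na(event) & nzchar(event) & !is.na(year)
  rejected <- sum(!ok)
  coerced <- version_coerced + sex_coerced + age_coerced +
    region_coerced + outcome_coerced
  if (rejected > 0L) {
    warning(sprintf("rejected %d row(s) with unparseable mandatory fields", rejected))
  }
  if (coerced > 0L) {
    warning(sprintf("coerced %d optional field value(s) to unknown/missing", coerced))
  }

  dt <- data.table::data.table(
    case_id = case_id[ok], version = version[ok], drug_name = drug_name[ok],
    role = role[ok], event = event[ok], sex = sex[ok], age_years = age[ok],
    region = region[ok], outcome = outcome[ok], year = year[ok]
  )
  grouped <- dt[, list(
    drug_name = drug_name[1L], role = role[1L],
    events = list(unique(event)), sex = sex[1L], age_years = age_years[1L],
    region = region[1L], outcome = outcome[1L], year = year[1L]
  ), by = c("case_id", "version")]
  reports <- data.table::setDF(grouped)
  # restore canonical column order
  reports <- reports[, c("case_id", "version", "drug_name", "role", "events",
                         "sex", "age_years", "region", "outcome", "year")]
  new_report_set(reports, provenance = path,
                 log = list(rows_read = nrow(raw), rows_rejected = rejected,
                            fields_coerced = as.integer(coerced)))
}

#' Write a report set to a delimited file
#'
#' Emits the long one-row-per-report-event format [read_reports()] consumes,
#' using the same dialect, so that write-then-read round-trips a valid set.
#'
#' @param rs A `pv_report_set`.
#' @param path Output path.
#' @param dialect A [report_dialect()].
#' @return `path`, invisibly.
#' @export
write_reports <- function(rs, path, dialect = report_dialect()) {
  stopifnot(inherits(rs, "pv_report_set"))
  r <- rs$reports
  n_ev <- lengths(r$events)
  idx <- rep.int(seq_len(nrow(r)), n_ev)
  long <- data.table::data.table(
    case_id = r$case_id[idx], version = r$version[idx],
    drug_name = r$drug_name[idx], role = r$role[idx],
    event = unlist(r$events, use.names = FALSE),
    sex = r$sex[idx], age_years = r$age_years[idx],
    region = r$region[idx], outcome = r$outcome[idx], year = r$year[idx]
  )
  cols <- dialect$columns
  names(long) <- unname(cols[c("case_id", "version", "drug_name", "role",
                               "event", "sex", "age", "region", "outcome",
                               "year")])
  data.table::fwrite(long, path, sep = dialect$delim, na = "", quote = FALSE)
  invisible(path)
}

#' Read a PT-to-SOC mapping table
#'
#' Two-column delimited file mapping each MedDRA-style preferred term (PT) to
#' exactly one system organ class (SOC). Header row required; columns matched
#' case-insensitively as `pt` and `soc`.
#'
#' @param path Path to a TSV (or CSV) file.
#' @param delim Field delimiter.
#' @return A `pv_meddra_map`: named character vector `PT -> SOC`.
#' @export
read_meddra_map <- function(path, delim = "\t") {
  if (!file.exists(path)) stop("mapping file not found: ", path)
  raw <- data.table::fread(path, sep = delim, header = TRUE,
                           colClasses = "character")
  names(raw) <- tolower(names(raw))
  if (!all(c("pt", "soc") %in% names(raw))) {
    stop("mapping file must have columns 'pt' and 'soc'")
  }
  if (nrow(raw) == 0L) stop("mapping file has no rows")
  meddra_map(raw$pt, raw$soc)
}

#' Construct a PT-to-SOC map from vectors
#'
#' @param pt Character vector of preferred terms.
#' @param soc Character vector of system organ classes, same length.
#' @return A `pv_meddra_map`.
#' @export
meddra_map <- function(pt, soc) {
  pt <- trimws(pt); soc <- trimws(soc)
  if (length(pt) != length(soc)) stop("pt and soc must have equal length")
  if (any(!nzchar(pt)) || any(!nzchar(soc)) || anyNA(pt) || anyNA(soc)) {
    stop("empty PT or SOC values are not allowed")
  }
  dup <- duplicated(pt)
  if (any(dup)) {
    first_soc <- soc[match(pt, pt)]
    conflict <- pt[dup][soc[dup] != first_soc[dup]]
    if (length(conflict)) {
      stop("conflicting SOC for PT(s): ", paste(unique(conflict), collapse = ", "))
    }
    pt <- pt[!dup]; soc <- soc[!dup]
  }
  structure(stats::setNames(soc, pt), class = "pv_meddra_map")
}

#' @export
print.pv_meddra_map <- function(x, ...) {
  cat(sprintf("<pv_meddra_map> %d PTs over %d SOCs\n",
              length(x), length(unique(unclass(x)))))
  invisible(x)
}

#' Deduplicate a report set by case
#'
#' Spontaneous-report databases carry multiple versions of a case as it is
#' revised; analysis uses the latest. For each `case_id` the record with the
#' highest `version` is retained; ties on version are broken by the last
#' occurrence in input order. Output order is stable by first appearance of
#' each `case_id`. Idempotent.
#'
#' @param rs A `pv_report_set`.
#' @return A `pv_report_set` with unique `case_id`s.
#' @export
deduplicate <- function(rs) {
  stopifnot(inherits(rs, "pv_report_set"))
  r <- rs$reports
  if (nrow(r) == 0L) return(rs)
  maxv <- stats::ave(r$version, r$case_id, FUN = max)
  cand <- which(r$version == maxv)
  # among candidates, last occurrence per case_id wins the version tie
  keep <- cand[!duplicated(r$case_id[cand], fromLast = TRUE)]
  # stable order by first appearance of case_id
  first_seen <- match(r$case_id[keep], unique(r$case_id))
  keep <- keep[order(first_seen)]
  out <- r[keep, , drop = FALSE]
  rownames(out) <- NULL
  new_report_set(out, provenance = rs$provenance, log = rs$log)
}

#' Drug query: canonical name plus synonyms
#'
#' Product-name matching in spontaneous-report data requires a synonym list
#' (trade names, formulations). Matching downstream is exact after
#' case-folding and whitespace trimming, not substring matching.
#'
#' @param canonical_name Canonical drug name.
#' @param synonyms Character vector of alternative product names; the
#'   canonical name is always included.
#' @return A `pv_drug_query`.
#' @export
drug_query <- function(canonical_name, synonyms = character()) {
  canonical_name <- trimws(canonical_name)
  if (!nzchar(canonical_name)) stop("canonical_name must be non-empty")
  syn <- unique(tolower(trimws(c(canonical_name, synonyms))))
  syn <- syn[nzchar(syn)]
  if (!length(syn)) stop("synonym set must be non-empty")
  structure(list(canonical_name = canonical_name, synonyms = syn),
            class = "pv_drug_query")
}

#' Partition reports into target-drug and background sets
#'
#' Applies the role and receipt-year filters, then splits the surviving
#' reports by drug-name match against the query's synonyms (case-insensitive,
#' whitespace-trimmed, exact). The two partitions are disjoint and together
#' contain every report passing the role/year filters.
#'
#' @param rs A deduplicated `pv_report_set`.
#' @param drug A [drug_query()].
#' @param role_filter Character vector of roles to keep
#'   (default `"primary_suspect"`).
#' @param year_range `c(start, end)` inclusive receipt-year window, or `NULL`
#'   for no year filter.
#' @return A list with `drug_reports` and `background_reports`, both
#'   `pv_report_set`s.
#' @export
filter_reports <- function(rs, drug, role_filter = "primary_suspect",
                           year_range = NULL) {
  stopifnot(inherits(rs, "pv_report_set"), inherits(drug, "pv_drug_query"))
  if (!length(drug$synonyms)) stop("synonym set must be non-empty")
  bad_roles <- setdiff(role_filter, ROLE_LEVELS)
  if (length(bad_roles)) stop("unknown role(s): ", paste(bad_roles, collapse = ", "))
  r <- rs$reports
  pass <- r$role %in% role_filter
  if (!is.null(year_range)) {
    stopifnot(length(year_range) == 2L)
    pass <- pass & r$year >= year_range[1L] & r$year <= year_range[2L]
  }
  is_drug <- tolower(trimws(r$drug_name)) %in% drug$synonyms
  mk <- function(rows, tag) {
    out <- r[rows, , drop = FALSE]
    rownames(out) <- NULL
    new_report_set(out, provenance = paste0(rs$provenance, " [", tag, "]"),
                   log = rs$log)
  }
  list(drug_reports = mk(pass & is_drug, drug$canonical_name),
       background_reports = mk(pass & !is_drug, "background"))
}
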