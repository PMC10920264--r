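#' Aggregate per-PT case counts to system-organ-class summary rows
#'
#' The SOC "case number" is the sum over the SOC's preferred terms of the
#' per-PT case counts — a case reporting two PTs of one SOC contributes
#' twice, the record-level convention of published ADR summary tables.
#' Percentages use the grand total of all rows as denominator, rounded
#' half-up to two decimals.
#'
#' @param pt_counts Named integer vector (PT -> case count) or data.frame
#'   with columns `pt` and `count`.
#' @param map A `pv_meddra_map`. PTs absent from the map are collected under
#'   `"Unmapped"` with a warning.
#' @return data.frame `soc, case_number, pt_count, percentage`, sorted by
#'   `case_number` descending (ties: lexicographic SOC). `pt_count` is the
#'   number of distinct PTs with a positive count under the SOC.
#' @export
soc_summary <- function(pt_counts, map) {
  stopifnot(inherits(map, "pv_meddra_map"))
  if (is.data.frame(pt_counts)) {
    stopifnot(all(c("pt", "count") %in% names(pt_counts)))
    counts <- stats::setNames(pt_counts$count, pt_counts$pt)
  } else {
    counts <- pt_counts
  }
  if (is.null(names(counts))) stop("pt_counts must carry PT names")
  if (any(counts < 0)) stop("negative case count")
  counts <- counts[counts > 0]
  if (!length(counts)) {
    return(data.frame(soc = character(), case_number = integer(),
                      pt_count = integer(), percentage = numeric()))
  }
  soc <- unname(unclass(map)[names(counts)])
  if (anyNA(soc)) {
    warning(sprintf("%d PT(s) not in the mapping; collected under 'Unmapped'",
                    sum(is.na(soc))))
    soc[is.na(soc)] <- "Unmapped"
  }
  case_number <- tapply(as.integer(counts), soc, sum)
  pt_count <- tapply(names(counts), soc, function(p) length(unique(p)))
  out <- data.frame(soc = names(case_number),
                    case_number = as.integer(case_number),
                    pt_count = as.integer(pt_count[names(case_number)]),
                    stringsAsFactors = FALSE)
  out$percentage <- percentage(out$case_number, sum(out$case_number))
  out <- out[order(-out$case_number, out$soc), , drop = FALSE]
  rownames(out) <- NULL
  out
}

default_age_bands <- function() c(0, 18, 45, 65, 75)

age_band_labels <- function(edges) {
  if (is.unsorted(edges, strictly = TRUE)) stop("age band edges must be increasing")
  n <- length(edges)
  c(sprintf("[%g,%g)", edges[-n], edges[-1L]), sprintf("[%g,Inf)", edges[n]))
}

#' Cohort characteristics of a report set
#'
#' Tabulates sex, age band, region, outcome and receipt year, each with a
#' companion percentage over the total number of reports (half-up, two
#' decimals). Every report falls in exactly one category per dimension;
#' missing ages go to the `"missing"` band. Age bands are half-open
#' `[low, high)` with the final band open-ended, so a 65-year-old falls in
#' the band starting at 65.
#'
#' @param rs A deduplicated `pv_report_set`.
#' @param age_bands Increasing numeric band edges; default
#'   `c(0, 18, 45, 65, 75)` giving bands `[0,18) ... [75,Inf)`.
#' @return A `pv_cohort_summary`: list with `total_reports` and data.frames
#'   `sex, age, region, outcome, year` (`category, count, percentage`).
#' @export
cohort_characteristics <- function(rs, age_bands = default_age_bands()) {
  stopifnot(inherits(rs, "pv_report_set"))
  r <- rs$reports
  total <- nrow(r)
  if (total == 0L) stop("empty report set")
  labels <- age_band_labels(age_bands)
  band <- rep("missing", total)
  ok <- !is.na(r$age_years)
  band[ok] <- labels[findInterval(r$age_years[ok], age_bands)]
  tab <- function(x, levels) {
    counts <- table(factor(x, levels = levels))
    data.frame(category = names(counts), count = as.integer(counts),
               percentage = percentage(as.integer(counts), total),
               stringsAsFactors = FALSE)
  }
  out <- list(
    total_reports = total,
    sex = tab(r$sex, SEX_LEVELS),
    age = tab(band, c(labels, "missing")),
    region = tab(r$region, REGION_LEVELS),
    outcome = tab(r$outcome, OUTCOME_LEVELS),
    year = tab(r$year, sort(unique(r$year)))
  )
  structure(out, class = "pv_cohort_summary")
}

#' @export
print.pv_cohort_summary <- function(x, ...) {
  cat(sprintf("<pv_cohort_summary> %d reports\n", x$total_reports))
  for (dim in c("sex", "age", "region", "outcome", "year")) {
    d <- x[[dim]]
    top <- d[which.max(d$count), ]
    cat(sprintf("  %-8s top: %s (%d, %.2f%%)\n", dim, top$category,
                top$count, top$percentage))
  }
  invisible(x)
}
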