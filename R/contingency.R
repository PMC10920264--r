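# 2x2 disproportionality tables.
#
# Counting unit is the report (distinct case), not the report-event row: a
# case mentioning a PT counts once toward cell a (or c) however many rows
# mentioned it. Cells:
#   a  target-drug reports mentioning the PT
#   b  target-drug reports not mentioning it
#   c  background reports mentioning it
#   d  background reports not mentioning it

count_events <- function(rs) {
  ev <- unlist(rs$reports$events, use.names = FALSE)
  if (is.null(ev) || !length(ev)) return(integer())
  tab <- table(ev)
  stats::setNames(as.integer(tab), names(tab))
}

target_label <- function(drug_reports, drug) {
  if (!is.null(drug)) return(drug)
  dn <- unique(drug_reports$reports$drug_name)
  if (length(dn) == 1L) dn else "target"
}

#' Build the 2x2 contingency table for one drug-event pair
#'
#' @param drug_reports `pv_report_set` of target-drug reports.
#' @param background_reports `pv_report_set` of all other reports (disjoint
#'   partition from [filter_reports()]).
#' @param event PT string.
#' @param drug Optional drug label for the output (defaults to the single
#'   drug name present in `drug_reports`).
#' @return One-row data.frame `drug, pt, a, b, c, d`. Zero cells are legal
#'   here; they are handled by the estimators' zero policies downstream.
#' @export
build_table <- function(drug_reports, background_reports, event, drug = NULL) {
  stopifnot(inherits(drug_reports, "pv_report_set"),
            inherits(background_reports, "pv_report_set"),
            is.character(event), length(event) == 1L, nzchar(event))
  has <- function(rs) sum(vapply(rs$reports$events, function(e) event %in% e,
                                 logical(1)))
  a <- has(drug_reports)
  c_ <- has(background_reports)
  data.frame(drug = target_label(drug_reports, drug), pt = event,
             a = a, b = n_reports(drug_reports) - a,
             c = c_, d = n_reports(background_reports) - c_,
             stringsAsFactors = FALSE)
}

#' Build 2x2 tables for every preferred term
#'
#' One table per PT in the universe. For a fixed pair of partitions every
#' table shares the same margins `a + b` and `c + d` (the partition sizes).
#'
#' @inheritParams build_table
#' @param universe Character vector of PTs, or `NULL` to use every PT
#'   observed in either partition.
#' @param restrict_observed When `TRUE` (default) drop PTs with no mention in
#'   either partition (all-zero tables are uninformative).
#' @return data.frame `drug, pt, a, b, c, d`, one row per PT, ordered by PT.
#' @export
build_all_tables <- function(drug_reports, background_reports, universe = NULL,
                             restrict_observed = TRUE, drug = NULL) {
  stopifnot(inherits(drug_reports, "pv_report_set"),
            inherits(background_reports, "pv_report_set"))
  ca <- count_events(drug_reports)
  cc <- count_events(background_reports)
  observed <- sort(unique(c(names(ca), names(cc))))
  pts <- if (is.null(universe)) observed else sort(unique(universe))
  if (restrict_observed) pts <- intersect(pts, observed)
  if (!length(pts)) {
    return(data.frame(drug = character(), pt = character(), a = integer(),
                      b = integer(), c = integer(), d = integer(),
                      stringsAsFactors = FALSE))
  }
  a <- ifelse(pts %in% names(ca), ca[pts], 0L)
  c_ <- ifelse(pts %in% names(cc), cc[pts], 0L)
  data.frame(drug = target_label(drug_reports, drug), pt = pts,
             a = as.integer(a), b = n_reports(drug_reports) - as.integer(a),
             c = as.integer(c_),
             d = n_reports(background_reports) - as.integer(c_),
             stringsAsFactors = FALSE, row.names = NULL)
}
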