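#' @importFrom tools md5sum
#' @importFrom jsonlite write_json
#' @importFrom yaml read_yaml
NULL

as_drug_queries <- function(drug_config) {
  if (is.character(drug_config) && length(drug_config) == 1L &&
      file.exists(drug_config)) {
    drug_config <- yaml::read_yaml(drug_config)
  }
  if (inherits(drug_config, "pv_drug_query")) drug_config <- list(drug_config)
  lapply(drug_config, function(d) {
    if (inherits(d, "pv_drug_query")) return(d)
    drug_query(d$canonical_name %||% d$name, unlist(d$synonyms))
  })
}

as_criteria <- function(criteria_config) {
  if (is.null(criteria_config)) return(screening_criteria())
  if (inherits(criteria_config, "pv_criteria")) return(criteria_config)
  if (is.character(criteria_config) && length(criteria_config) == 1L &&
      file.exists(criteria_config)) {
    criteria_config <- yaml::read_yaml(criteria_config)
  }
  do.call(screening_criteria, criteria_config)
}

write_tsv_plain <- function(df, path) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}

#' Run the full disproportionality pipeline
#'
#' End to end: read reports and the PT-to-SOC map, deduplicate, and for each
#' configured drug partition the reports, build all 2x2 tables, screen
#' against the criteria, rank signals both by ROR lower confidence bound and
#' by raw case count, aggregate the signal PTs to SOC level, and summarise
#' cohort demographics. All tables are written as TSV plus a JSON run
#' manifest (input hashes, configuration echo, rejection counts); re-running
#' on identical inputs reproduces identical files.
#'
#' @param reports_path Report file readable by [read_reports()].
#' @param meddra_path PT-to-SOC TSV readable by [read_meddra_map()].
#' @param drug_config List of drug specs (`canonical_name`, `synonyms`), a
#'   list of [drug_query()] objects, or a YAML file of the same shape.
#' @param criteria_config A [screening_criteria()], a list/YAML file of its
#'   arguments, or `NULL` for defaults.
#' @param out_dir Output directory (created if needed).
#' @param dialect Reader dialect.
#' @param role_filter Roles retained (default primary suspect only).
#' @param year_range Inclusive receipt-year window or `NULL`.
#' @param top_k Rows kept in the ranked signal tables (default 20).
#' @param age_bands Age band edges for the cohort summary.
#' @param yates,zero_policy Passed to [screen_tables()].
#' @return Invisibly, a named list (per drug) of the in-memory results:
#'   `stats`, `signals_by_ci`, `signals_by_count`, `soc`, `cohort`.
#' @export
run_pipeline <- function(reports_path, meddra_path, drug_config,
                         criteria_config = NULL, out_dir,
                         dialect = report_dialect(),
                         role_filter = "primary_suspect", year_range = NULL,
                         top_k = 20, age_bands = default_age_bands(),
                         yates = TRUE, zero_policy = "undefined") {
  queries <- as_drug_queries(drug_config)
  criteria <- as_criteria(criteria_config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  rs <- tryCatch(read_reports(reports_path, dialect),
                 error = function(e) stop("report_store: ", conditionMessage(e)))
  map <- tryCatch(read_meddra_map(meddra_path),
                  error = function(e) stop("meddra: ", conditionMessage(e)))
  deduped <- deduplicate(rs)

  results <- list()
  for (q in queries) {
    name <- q$canonical_name
    parts <- filter_reports(deduped, q, role_filter = role_filter,
                            year_range = year_range)
    tables <- build_all_tables(parts$drug_reports, parts$background_reports,
                               drug = name)
    stats <- tryCatch(
      screen_tables(tables, criteria, yates = yates, zero_policy = zero_policy),
      error = function(e) stop("disproportionality: ", conditionMessage(e)))
    by_ci <- rank_signals(stats, "by_ror_ci_low", top_k)
    by_count <- rank_signals(stats, "by_case_count", top_k)
    sig <- stats[stats$is_signal, , drop = FALSE]
    soc <- if (nrow(sig)) {
      soc_summary(stats::setNames(sig$a, sig$pt), map)
    } else {
      data.frame(soc = character(), case_number = integer(),
                 pt_count = integer(), percentage = numeric())
    }
    cohort <- if (n_reports(parts$drug_reports) > 0L) {
      cohort_characteristics(parts$drug_reports, age_bands)
    }

    slug <- gsub("[^a-z0-9]+", "_", tolower(name))
    write_signal_stats(stats, file.path(out_dir, paste0(slug, "_stats.tsv")))
    write_signal_stats(by_ci, file.path(out_dir, paste0(slug, "_signals_by_ci.tsv")))
    write_signal_stats(by_count, file.path(out_dir, paste0(slug, "_signals_by_count.tsv")))
    write_tsv_plain(soc, file.path(out_dir, paste0(slug, "_soc_summary.tsv")))
    if (!is.null(cohort)) {
      flat <- do.call(rbind, lapply(c("sex", "age", "region", "outcome", "year"),
                                    function(dim) {
        cbind(dimension = dim, cohort[[dim]])
      }))
      write_tsv_plain(flat, file.path(out_dir, paste0(slug, "_cohort.tsv")))
    }
    results[[name]] <- list(stats = stats, signals_by_ci = by_ci,
                            signals_by_count = by_count, soc = soc,
                            cohort = cohort,
                            n_drug_reports = n_reports(parts$drug_reports),
                            n_background_reports = n_reports(parts$background_reports))
  }

  manifest <- list(
    inputs = list(
      reports = list(path = reports_path,
                     md5 = unname(tools::md5sum(reports_path))),
      meddra = list(path = meddra_path,
                    md5 = unname(tools::md5sum(meddra_path)))
    ),
    config = list(
      drugs = lapply(queries, function(q) list(canonical_name = q$canonical_name,
                                               synonyms = q$synonyms)),
      criteria = unclass(criteria),
      role_filter = role_filter, year_range = year_range, top_k = top_k,
      age_bands = age_bands, yates = yates, zero_policy = zero_policy
    ),
    run_log = run_log(rs),
    n_reports_raw = n_reports(rs),
    n_reports_deduplicated = n_reports(deduped),
    per_drug = lapply(results, function(r) list(
      n_drug_reports = r$n_drug_reports,
      n_background_reports = r$n_background_reports,
      n_pts_screened = nrow(r$stats),
      n_signals = sum(r$stats$is_signal)
    ))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA,
                       null = "null")
  invisible(results)
}
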