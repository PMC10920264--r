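#' @importFrom stats qnorm
NULL

#' Screening criteria for joint ROR/PRR signal detection
#'
#' The PRR criterion requires `a >= min_n`, a chi-square statistic of at
#' least `min_chi2`, and `PRR >= min_prr`; the ROR criterion requires
#' `a >= min_n` and a lower 95\% confidence bound strictly above
#' `ror_ci_low`. A drug-event pair is a signal only when both criteria hold.
#'
#' @param min_n Minimum co-occurrence count `a` (default 3).
#' @param min_chi2 Minimum chi-square statistic (default 4).
#' @param min_prr Minimum PRR point estimate (default 2).
#' @param ror_ci_low Threshold the ROR lower confidence bound must exceed
#'   (strictly; default 1).
#' @param level Confidence level for the intervals (default 0.95).
#' @return A `pv_criteria`.
#' @export
screening_criteria <- function(min_n = 3, min_chi2 = 4, min_prr = 2,
                               ror_ci_low = 1, level = 0.95) {
  stopifnot(min_n > 0, min_chi2 > 0, min_prr > 0, ror_ci_low > 0,
            level > 0, level < 1)
  structure(list(min_n = min_n, min_chi2 = min_chi2, min_prr = min_prr,
                 ror_ci_low = ror_ci_low, level = level),
            class = "pv_criteria")
}

#' @export
print.pv_criteria <- function(x, ...) {
  cat(sprintf(
    "<pv_criteria> PRR: n>=%g & chi2>=%g & PRR>=%g; ROR: n>=%g & ci_low>%g (%.0f%% CI)\n",
    x$min_n, x$min_chi2, x$min_prr, x$min_n, x$ror_ci_low, 100 * x$level))
  invisible(x)
}

as_cells <- function(t) {
  stopifnot(is.data.frame(t), all(c("a", "b", "c", "d") %in% names(t)))
  if (any(t$a < 0 | t$b < 0 | t$c < 0 | t$d < 0)) stop("negative cell count")
  t
}

# Vectorised ROR with ln-scale Wald CI. Returns data.frame
# point/ci_low/ci_high/corrected; undefined estimates are NA rows.
ror_vec <- function(a, b, c, d, level = 0.95, zero_policy = "undefined") {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  zero <- a == 0 | b == 0 | c == 0 | d == 0
  corrected <- rep(FALSE, length(a))
  if (zero_policy == "haldane") {
    a <- a + 0.5 * zero; b <- b + 0.5 * zero
    c <- c + 0.5 * zero; d <- d + 0.5 * zero
    corrected <- zero
    defined <- rep(TRUE, length(a))
  } else {
    defined <- !zero
  }
  point <- ci_low <- ci_high <- rep(NA_real_, length(a))
  i <- which(defined)
  if (length(i)) {
    est <- (a[i] * d[i]) / (b[i] * c[i])
    se <- sqrt(1 / a[i] + 1 / b[i] + 1 / c[i] + 1 / d[i])
    z <- qnorm(1 - (1 - level) / 2)
    point[i] <- est
    ci_low[i] <- exp(log(est) - z * se)
    ci_high[i] <- exp(log(est) + z * se)
  }
  data.frame(point = point, ci_low = ci_low, ci_high = ci_high,
             corrected = corrected)
}

# Vectorised PRR with ln-scale Wald CI; undefined when a=0 or c=0 (no
# continuity correction for PRR).
prr_vec <- function(a, b, c, d, level = 0.95) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n1 <- a + b; n0 <- c + d
  defined <- a > 0 & c > 0 & n1 > 0 & n0 > 0
  point <- ci_low <- ci_high <- rep(NA_real_, length(a))
  i <- which(defined)
  if (length(i)) {
    est <- (a[i] / n1[i]) / (c[i] / n0[i])
    se <- sqrt(1 / a[i] - 1 / n1[i] + 1 / c[i] - 1 / n0[i])
    z <- qnorm(1 - (1 - level) / 2)
    point[i] <- est
    ci_low[i] <- exp(log(est) - z * se)
    ci_high[i] <- exp(log(est) + z * se)
  }
  data.frame(point = point, ci_low = ci_low, ci_high = ci_high)
}

# Vectorised 2x2 chi-square; Yates subtracts min(N/2, |ad-bc|) from |ad-bc|.
# Undefined (NA) when any margin is zero.
chi2_vec <- function(a, b, c, d, yates = TRUE) {
  a <- as.numeric(a); b <- as.numeric(b); c <- as.numeric(c); d <- as.numeric(d)
  n <- a + b + c + d
  m1 <- a + b; m0 <- c + d; k1 <- a + c; k0 <- b + d
  defined <- m1 > 0 & m0 > 0 & k1 > 0 & k0 > 0
  dev <- abs(a * d - b * c)
  if (yates) dev <- pmax(0, dev - n / 2)
  out <- rep(NA_real_, length(a))
  i <- which(defined)
  out[i] <- n[i] * dev[i]^2 / (m1[i] * m0[i] * k1[i] * k0[i])
  out
}

#' Reporting odds ratio with Wald confidence interval
#'
#' `ROR = (a d) / (b c)` with a normal-approximation interval on the log
#' scale, `SE = sqrt(1/a + 1/b + 1/c + 1/d)`. With a zero cell the estimate
#' is undefined under the default policy; the Haldane-Anscombe policy adds
#' 0.5 to every cell instead and flags the result as corrected.
#'
#' @param t One-row contingency data.frame (from [build_table()]).
#' @param level Confidence level.
#' @param zero_policy `"undefined"` or `"haldane"`.
#' @return A list `point, ci_low, ci_high, level, corrected`, or `NULL` when
#'   undefined.
#' @export
compute_ror <- function(t, level = 0.95,
                        zero_policy = c("undefined", "haldane")) {
  zero_policy <- match.arg(zero_policy)
  t <- as_cells(t)
  stopifnot(nrow(t) == 1L)
  r <- ror_vec(t$a, t$b, t$c, t$d, level, zero_policy)
  if (is.na(r$point)) return(NULL)
  list(point = r$point, ci_low = r$ci_low, ci_high = r$ci_high,
       level = level, corrected = r$corrected)
}

#' Proportional reporting ratio with Wald confidence interval
#'
#' `PRR = [a/(a+b)] / [c/(c+d)]` with log-scale
#' `SE = sqrt(1/a - 1/(a+b) + 1/c - 1/(c+d))`. Undefined when `a = 0` or
#' `c = 0` (no continuity correction is applied to PRR); `b = 0` is legal.
#'
#' @inheritParams compute_ror
#' @return A list `point, ci_low, ci_high, level`, or `NULL` when undefined.
#' @export
compute_prr <- function(t, level = 0.95) {
  t <- as_cells(t)
  stopifnot(nrow(t) == 1L, t$a + t$b > 0, t$c + t$d > 0)
  r <- prr_vec(t$a, t$b, t$c, t$d, level)
  if (is.na(r$point)) return(NULL)
  list(point = r$point, ci_low = r$ci_low, ci_high = r$ci_high, level = level)
}

#' Pearson chi-square statistic for a 2x2 table
#'
#' `N (ad - bc)^2 / [(a+b)(c+d)(a+c)(b+d)]`; the Yates-corrected variant
#' (default) shrinks `|ad - bc|` by `N/2`, clamped at zero. Symmetric under
#' swapping rows and under swapping columns. `NA` when a margin is zero.
#'
#' @inheritParams compute_ror
#' @param yates Apply the Yates continuity correction (default `TRUE`).
#' @return Non-negative scalar, or `NA` when undefined.
#' @export
compute_chi2 <- function(t, yates = TRUE) {
  t <- as_cells(t)
  stopifnot(nrow(t) == 1L)
  chi2_vec(t$a, t$b, t$c, t$d, yates)
}

#' Screen contingency tables against the joint ROR/PRR criteria
#'
#' Computes ROR, PRR and chi-square for each table and evaluates the two
#' screening criteria; an undefined statistic simply fails its criterion.
#'
#' @param tables data.frame of contingency tables (from
#'   [build_all_tables()]), columns `drug, pt, a, b, c, d`.
#' @param criteria A [screening_criteria()].
#' @param yates Yates correction for the chi-square (default `TRUE`).
#' @param zero_policy Zero-cell policy for the ROR, see [compute_ror()].
#' @return data.frame with one row per table: the cells plus `ror,
#'   ror_ci_low, ror_ci_high, prr, prr_ci_low, prr_ci_high, chi2, n,
#'   prr_met, ror_met, is_signal, corrected`.
#' @export
screen_tables <- function(tables, criteria = screening_criteria(),
                          yates = TRUE,
                          zero_policy = c("undefined", "haldane")) {
  zero_policy <- match.arg(zero_policy)
  stopifnot(inherits(criteria, "pv_criteria"))
  tables <- as_cells(tables)
  ror <- ror_vec(tables$a, tables$b, tables$c, tables$d, criteria$level,
                 zero_policy)
  prr <- prr_vec(tables$a, tables$b, tables$c, tables$d, criteria$level)
  chi2 <- chi2_vec(tables$a, tables$b, tables$c, tables$d, yates)
  n <- tables$a
  prr_met <- !is.na(prr$point) & !is.na(chi2) &
    n >= criteria$min_n & chi2 >= criteria$min_chi2 &
    prr$point >= criteria$min_prr
  ror_met <- !is.na(ror$ci_low) &
    n >= criteria$min_n & ror$ci_low > criteria$ror_ci_low
  out <- tables
  out$ror <- ror$point
  out$ror_ci_low <- ror$ci_low
  out$ror_ci_high <- ror$ci_high
  out$prr <- prr$point
  out$prr_ci_low <- prr$ci_low
  out$prr_ci_high <- prr$ci_high
  out$chi2 <- chi2
  out$n <- n
  out$prr_met <- prr_met
  out$ror_met <- ror_met
  out$is_signal <- prr_met & ror_met
  out$corrected <- ror$corrected
  out
}

#' Screen a single contingency table
#'
#' @inheritParams screen_tables
#' @param t One-row contingency data.frame.
#' @return One-row data.frame as in [screen_tables()].
#' @export
screen <- function(t, criteria = screening_criteria(), yates = TRUE,
                   zero_policy = c("undefined", "haldane")) {
  stopifnot(nrow(t) == 1L)
  screen_tables(t, criteria, yates, match.arg(zero_policy))
}

#' Rank screened drug-event pairs
#'
#' `by_ror_ci_low` keeps only pairs flagged as signals and ranks them by the
#' ROR lower confidence bound (the convention for disproportionality league
#' tables); `by_case_count` keeps every pair and ranks by raw case count `a`
#' (the convention of public ADR-count interfaces such as VigiAccess). Ties
#' are broken by larger `a`, then lexicographic PT.
#'
#' @param stats data.frame from [screen_tables()].
#' @param mode `"by_ror_ci_low"` or `"by_case_count"`.
#' @param top_k Number of rows to keep (default 20; `Inf` keeps all).
#' @return data.frame, ordered, at most `top_k` rows.
#' @export
rank_signals <- function(stats, mode = c("by_ror_ci_low", "by_case_count"),
                         top_k = 20) {
  mode <- match.arg(mode)
  stopifnot(is.data.frame(stats))
  if (mode == "by_ror_ci_low") {
    stats <- stats[!is.na(stats$is_signal) & stats$is_signal, , drop = FALSE]
    key <- stats$ror_ci_low
  } else {
    key <- stats$a
  }
  o <- order(-key, -stats$a, stats$pt)
  out <- stats[o, , drop = FALSE]
  if (is.finite(top_k)) out <- utils::head(out, top_k)
  rownames(out) <- NULL
  out
}

#' Export screened statistics as TSV
#'
#' Writes the [screen_tables()] output with float columns formatted to four
#' decimals.
#'
#' @param stats data.frame from [screen_tables()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_signal_stats <- function(stats, path) {
  out <- stats
  for (col in c("ror", "ror_ci_low", "ror_ci_high", "prr", "prr_ci_low",
                "prr_ci_high", "chi2")) {
    if (col %in% names(out)) out[[col]] <- fmt4(out[[col]])
  }
  data.table::fwrite(out, path, sep = "\t", quote = FALSE, na = "NA")
  invisible(path)
}
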