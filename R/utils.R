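#' Percentage with half-up rounding to two decimals
#'
#' Computes `100 * count / total` rounded half-up at two decimal places, the
#' convention used for every percentage this package prints. Half-up rounding
#' (0.125 -> 0.13) differs from R's [round()], which rounds half to even; the
#' published tables this package reproduces use half-up.
#'
#' The computation is carried out in exact integer arithmetic
#' (`floor((20000*count + total) / (2*total)) / 100`), so results are not
#' subject to binary floating-point representation of the quotient.
#'
#' @param count Non-negative integer count (vectorised), `count <= total`.
#' @param total Positive integer denominator.
#' @return Numeric vector of percentages in `[0, 100]`, two decimals.
#' @examples
#' percentage(16716, 55949) # 29.88
#' percentage(1, 800)       # 0.13 (half-up; round() would give 0.12)
#' @export
percentage <- function(count, total) {
  if (length(total) != 1L && length(total) != length(count)) {
    stop("`total` must be scalar or match `count` in length")
  }
  if (any(total <= 0)) stop("`total` must be positive")
  if (any(count < 0) || any(count > total)) {
    stop("`count` must be in [0, total]")
  }
  if (any(count != floor(count)) || any(total != floor(total))) {
    stop("`count` and `total` must be whole numbers")
  }
  # exact: round_half_up(10000*count/total) / 100, all quantities < 2^53
  ((20000 * count + total) %/% (2 * total)) / 100
}

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    }
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# Format a numeric column for TSV export: 4 decimals, NA -> "NA".
fmt4 <- function(x) ifelse(is.na(x), NA_character_, sprintf("%.4f", x))
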