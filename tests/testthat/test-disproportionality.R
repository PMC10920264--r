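test_that("ROR point and Wald interval match hand values", {
  # symmetric table: point 1, interval straddles 1
  s <- compute_ror(ct(7, 7, 7, 7))
  expect_equal(s$point, 1)
  expect_lt(s$ci_low, 1); expect_gt(s$ci_high, 1)

  r <- compute_ror(ct(10, 90, 100, 9800))
  expect_equal(r$point, 98000 / 9000, tolerance = 1e-12)
  # frozen from exp(log(ROR) -/+ qnorm(.975) * sqrt(1/10+1/90+1/100+1/9800))
  expect_equal(r$ci_low, 5.503411, tolerance = 1e-6)
  expect_equal(r$ci_high, 21.544437, tolerance = 1e-6)
  expect_false(r$corrected)
})

test_that("zero-cell policy: undefined by default, Haldane-Anscombe optional", {
  z <- ct(0, 100, 10, 9890)
  expect_null(compute_ror(z))
  h <- compute_ror(z, zero_policy = "haldane")
  expect_true(h$corrected)
  expect_equal(h$point, (0.5 * 9890.5) / (100.5 * 10.5), tolerance = 1e-12)
  # non-zero tables are not corrected under haldane
  expect_false(compute_ror(ct(5, 5, 5, 5), zero_policy = "haldane")$corrected)
})

test_that("PRR matches hand values; b = 0 legal, a = 0 or c = 0 undefined", {
  expect_equal(compute_prr(ct(7, 7, 7, 7))$point, 1)
  expect_equal(compute_prr(ct(10, 90, 100, 9800))$point, 9.9, tolerance = 1e-12)
  expect_equal(compute_prr(ct(3, 0, 50, 5000))$point, 1 / (50 / 5050),
               tolerance = 1e-12)
  expect_null(compute_prr(ct(0, 100, 10, 9890)))
  expect_null(compute_prr(ct(10, 90, 0, 9890)))
})

test_that("chi-square matches the closed form and is symmetric", {
  expect_equal(compute_chi2(ct(7, 7, 7, 7), yates = FALSE), 0)
  expect_equal(compute_chi2(ct(10, 90, 100, 9800), yates = FALSE),
               10000 * (10 * 9800 - 90 * 100)^2 /
                 (100 * 9900 * 110 * 9890), tolerance = 1e-12)
  # row swap and column swap leave it unchanged
  expect_equal(compute_chi2(ct(100, 9800, 10, 90)),
               compute_chi2(ct(10, 90, 100, 9800)))
  expect_equal(compute_chi2(ct(90, 10, 9800, 100)),
               compute_chi2(ct(10, 90, 100, 9800)))
  # Yates shrinkage clamps at zero near independence
  expect_equal(compute_chi2(ct(5, 5, 5, 5), yates = TRUE), 0)
  # zero margin undefined
  expect_true(is.na(compute_chi2(ct(0, 0, 10, 10))))
})

test_that("point estimates match independent reference routines", {
  set.seed(101)
  n <- 1000
  a <- sample(1:100000, n, TRUE); b <- sample(1:100000, n, TRUE)
  cc <- sample(1:100000, n, TRUE); d <- sample(1:100000, n, TRUE)
  worst_or <- 0; worst_cy <- 0; worst_cn <- 0
  for (i in seq_len(n)) {
    t <- ct(a[i], b[i], cc[i], d[i])
    ref <- ref_odds_ratio(a[i], b[i], cc[i], d[i])
    worst_or <- max(worst_or, abs(compute_ror(t)$point - ref) / ref)
    worst_cy <- max(worst_cy, abs(compute_chi2(t, TRUE) - ref_chi2(a[i], b[i], cc[i], d[i], TRUE)))
    worst_cn <- max(worst_cn, abs(compute_chi2(t, FALSE) - ref_chi2(a[i], b[i], cc[i], d[i], FALSE)))
  }
  expect_lt(worst_or, 1e-10)
  expect_lt(worst_cy, 1e-8)
  expect_lt(worst_cn, 1e-8)
})

test_that("sign agreement and ROR >= PRR >= 1 ordering hold on random tables", {
  set.seed(7)
  for (i in 1:200) {
    a <- sample(1:500, 1); b <- sample(1:500, 1)
    cc <- sample(1:500, 1); d <- sample(1:500, 1)
    t <- ct(a, b, cc, d)
    ror <- compute_ror(t)$point
    prr <- compute_prr(t)$point
    ad_gt_bc <- a * d > b * cc
    expect_equal(ror > 1, ad_gt_bc)
    expect_equal(prr > 1, ad_gt_bc)
    if (ror > 1) {
      expect_true(ror >= prr && prr >= 1)
    } else if (ror < 1) {
      expect_true(ror <= prr && prr <= 1)
    }
  }
})

test_that("joint screening applies both criteria with undefined = fail", {
  # the worked example passes everything
  s <- screen(ct(10, 90, 100, 9800))
  expect_true(s$prr_met); expect_true(s$ror_met); expect_true(s$is_signal)
  expect_equal(s$n, 10)

  # a = 2 never signals however extreme the disproportionality
  s2 <- screen(ct(2, 1, 1, 100000))
  expect_gt(s2$ror, 1000)
  expect_false(s2$is_signal)

  # null table: PRR = 1 < 2 fails
  s3 <- screen(ct(50, 50, 50, 50))
  expect_false(s3$prr_met)
  expect_false(s3$is_signal)

  # undefined statistics fail their criterion quietly
  s4 <- screen(ct(0, 100, 10, 9890))
  expect_false(s4$prr_met); expect_false(s4$ror_met); expect_false(s4$is_signal)
  expect_true(s4$is_signal == (s4$prr_met && s4$ror_met))
})

test_that("each screening threshold flips exactly its own criterion", {
  t <- ct(10, 90, 100, 9800)
  base <- screen(t)
  eps <- 1e-9

  # chi-square threshold straddling the table's statistic
  lo <- screen(t, screening_criteria(min_chi2 = base$chi2 * (1 - eps)))
  hi <- screen(t, screening_criteria(min_chi2 = base$chi2 * (1 + eps)))
  expect_true(lo$prr_met); expect_false(hi$prr_met)
  expect_true(lo$ror_met && hi$ror_met) # ROR criterion untouched
  expect_true(lo$is_signal); expect_false(hi$is_signal)

  # PRR threshold: table with PRR exactly 2 meets min_prr = 2 (>=), fails 2.01
  t2 <- ct(20, 80, 100, 900) # 0.2 / 0.1 = 2
  expect_equal(screen(t2)$prr, 2)
  expect_true(screen(t2, screening_criteria(min_prr = 1.99))$prr_met)
  expect_true(screen(t2, screening_criteria(min_prr = 2))$prr_met)
  expect_false(screen(t2, screening_criteria(min_prr = 2.01))$prr_met)

  # ROR lower-bound threshold is strict
  lo2 <- screen(t, screening_criteria(ror_ci_low = base$ror_ci_low * (1 - eps)))
  hi2 <- screen(t, screening_criteria(ror_ci_low = base$ror_ci_low * (1 + eps)))
  expect_true(lo2$ror_met); expect_false(hi2$ror_met)
  expect_true(lo2$prr_met && hi2$prr_met)
  # exactly at the bound: strict > fails
  at <- screen(t, screening_criteria(ror_ci_low = base$ror_ci_low))
  expect_false(at$ror_met)

  # n threshold: a = 3 passes min_n = 3, a = 2 fails
  expect_true(screen(ct(3, 7, 30, 9000))$is_signal)
  expect_false(screen(ct(2, 8, 20, 9000))$is_signal)
})

test_that("screening is monotone under scaling all cells up", {
  set.seed(17)
  for (i in 1:50) {
    a <- sample(3:30, 1); b <- sample(1:300, 1)
    cc <- sample(1:300, 1); d <- sample(100:5000, 1)
    s1 <- screen(ct(a, b, cc, d))
    if (!s1$is_signal) next
    for (k in c(2L, 5L)) {
      sk <- screen(ct(a * k, b * k, cc * k, d * k))
      expect_true(sk$is_signal,
                  label = sprintf("scaling (%d,%d,%d,%d) by %d", a, b, cc, d, k))
    }
  }
})

test_that("CI coverage at true OR 3 is nominal", {
  # binomial rows with odds 1/3 vs 1/9 (OR = 3), E[a] = 30
  set.seed(23)
  n1 <- 120; p1 <- 0.25; n0 <- 10000; p0 <- 0.1
  hits <- 0L; used <- 0L
  for (r in 1:2000) {
    a <- stats::rbinom(1, n1, p1); cc <- stats::rbinom(1, n0, p0)
    est <- compute_ror(ct(a, n1 - a, cc, n0 - cc))
    if (is.null(est)) next
    used <- used + 1L
    if (est$ci_low <= 3 && est$ci_high >= 3) hits <- hits + 1L
  }
  expect_gt(used, 1900)
  expect_gte(hits / used, 0.93)
  expect_lte(hits / used, 0.97)
})

test_that("ranking honours mode, tie-breaks and truncation", {
  mk <- function(pt, a, ci_low, is_signal = TRUE) {
    data.frame(drug = "x", pt = pt, a = a, b = 1, c = 1, d = 1,
               ror = ci_low + 1, ror_ci_low = ci_low, ror_ci_high = ci_low + 2,
               prr = 2, prr_ci_low = 1, prr_ci_high = 3, chi2 = 10, n = a,
               prr_met = is_signal, ror_met = is_signal, is_signal = is_signal,
               corrected = FALSE, stringsAsFactors = FALSE)
  }
  stats <- rbind(mk("ipf", 40, 52.21), mk("dlco_down", 40, 48.29),
                 mk("tie_small", 4, 10), mk("tie_big", 40, 10),
                 mk("notsig", 1000, 99, is_signal = FALSE))
  r <- rank_signals(stats, "by_ror_ci_low", top_k = Inf)
  expect_equal(r$pt, c("ipf", "dlco_down", "tie_big", "tie_small"))
  # non-signals excluded in CI mode, retained in count mode
  expect_false("notsig" %in% r$pt)
  rc <- rank_signals(stats, "by_case_count", top_k = 3)
  expect_equal(rc$pt[1], "notsig")
  expect_equal(nrow(rc), 3L)

  # count ranking reproduces a known descending count ordering
  counts <- rbind(mk("death", 6240, 2), mk("nausea", 5013, 2),
                  mk("fatigue", 3760, 2))
  expect_equal(rank_signals(counts[c(2, 3, 1), ], "by_case_count")$pt,
               c("death", "nausea", "fatigue"))
  # equal key: lexicographic PT as final tie-break
  ties <- rbind(mk("zeta", 10, 5), mk("alpha", 10, 5))
  expect_equal(rank_signals(ties, "by_case_count")$pt, c("alpha", "zeta"))
})
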