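# BP parameter extraction, error metrics, BHS grading, AAMI compliance,
# Bland-Altman agreement, and the aggregated evaluation report.

test_that("extract_bp takes segment extrema and the standard mean pressure", {
  bp <- extract_bp(c(80, 95, 120, 100, 85))
  expect_equal(bp$sbp, 120)
  expect_equal(bp$dbp, 80)
  expect_equal(bp$mbp, (120 + 2 * 80) / 3, tolerance = 1e-9)
  expect_equal(extract_bp(rep(100, 5)),
               tibble::tibble(sbp = 100, dbp = 100, mbp = 100))
  set.seed(61)
  for (i in 1:10) {
    w <- rnorm(200, 100, 20)
    bp <- extract_bp(w)
    # brute-force scan oracle
    mx <- -Inf; mn <- Inf
    for (v in w) { if (v > mx) mx <- v; if (v < mn) mn <- v }
    expect_equal(c(bp$sbp, bp$dbp), c(mx, mn))
    expect_true(bp$dbp <= bp$mbp && bp$mbp <= bp$sbp)
  }
  expect_error(extract_bp(c(1, NA)), "finite")
  expect_error(extract_bp(numeric(0)), "non-empty")
})

test_that("bp_metrics reproduces hand-computed values and stays self-consistent", {
  m <- bp_metrics(c(1, 2, 3), c(2, 2, 2))
  expect_equal(m$me, 0)
  expect_equal(m$mae, 2 / 3, tolerance = 1e-4)
  expect_equal(m$mse, 2 / 3, tolerance = 1e-4)
  expect_equal(m$std_eq20, sqrt(2 / 3), tolerance = 1e-4)  # 0.8165
  expect_equal(m$r2, 0)
  # perfect prediction
  y <- rnorm(50, 100, 10)
  mp <- bp_metrics(y, y)
  expect_equal(c(mp$me, mp$mae, mp$mse, mp$std_eq20), rep(0, 4))
  expect_equal(c(mp$r2, mp$r), c(1, 1))
  # correlation is scale/offset invariant and matches cor()
  set.seed(62)
  a <- rnorm(100); b <- 2 * a + 1
  expect_equal(bp_metrics(a, b)$r, 1, tolerance = 1e-12)
  for (i in 1:5) {
    u <- rnorm(60, 100, 15); v <- u + rnorm(60, 0, 5)
    m2 <- bp_metrics(u, v)
    expect_equal(m2$r, stats::cor(u, v), tolerance = 1e-10)
    expect_equal(m2$std_eq20^2, m2$mse, tolerance = 1e-9)
    expect_gte(m2$mae, abs(m2$me))
    expect_gte(m2$mse, 0)
  }
  expect_warning(bp_metrics(rep(5, 10), rnorm(10)), "undefined")
})

test_that("BHS grading applies the per-threshold minima and worst-of-three rule", {
  expect_equal(bhs_grade(pct = c(62.08, 80.52, 89.88))$grade, "C")
  expect_equal(bhs_grade(pct = c(81.44, 90.38, 95.79))$grade, "A")
  expect_equal(bhs_grade(pct = c(100, 100, 100))$grade, "A")
  expect_equal(bhs_grade(pct = c(30, 50, 70))$grade, "D")
  # exact grade boundaries are inclusive; comparison at one-decimal precision
  expect_equal(bhs_grade(pct = c(60, 85, 95))$grade, "A")
  expect_equal(bhs_grade(pct = c(59.9, 85, 95))$grade, "B")
  expect_equal(bhs_grade(pct = c(79.09, 89.96, 94.95))$grade, "A")
  expect_equal(bhs_grade(pct = c(79.09, 89.96, 94.95), tol = 0)$grade, "B")
  expect_equal(bhs_grade(pct = c(50, 75, 90))$grade, "B")
  expect_equal(bhs_grade(pct = c(40, 65, 85))$grade, "C")
  expect_equal(bhs_grade(pct = c(39.9, 65, 85))$grade, "D")
  # percentages from raw errors use inclusive thresholds and are monotone
  g <- bhs_grade(c(0, 3, 5, 7, 10, 12, 15, 20))
  expect_equal(g$pct5, 100 * 3 / 8)
  expect_equal(g$pct10, 100 * 5 / 8)
  expect_equal(g$pct15, 100 * 7 / 8)
  set.seed(63)
  for (i in 1:5) {
    gg <- bhs_grade(abs(rnorm(100, 0, 8)))
    expect_true(gg$pct5 <= gg$pct10 && gg$pct10 <= gg$pct15)
  }
})

test_that("AAMI verdicts use inclusive limits on ME, SD and subject count", {
  expect_true(aami_check(-0.15, 6.71, 244)$pass)
  expect_true(aami_check(-0.54, 4.54, 244)$pass)
  expect_false(aami_check(5.1, 7.0, 100)$pass)   # ME out of range
  expect_false(aami_check(0, 8.5, 100)$pass)     # SD out of range
  expect_false(aami_check(0, 5, 84)$pass)        # too few subjects
  expect_true(aami_check(5, 8, 85)$pass)         # boundaries inclusive
})

test_that("Bland-Altman limits are mean +/- 1.96 population SD of differences", {
  z <- rnorm(20, 100, 10)
  ba0 <- bland_altman(z, z)
  expect_equal(c(ba0$loa_lower, ba0$loa_upper), c(0, 0))
  ba <- bland_altman(c(1, 1), c(0, 2))           # d = (-1, +1)
  expect_equal(ba$mean_diff, 0)
  expect_equal(ba$sd_diff, 1)
  expect_equal(c(ba$loa_lower, ba$loa_upper), c(-1.96, 1.96))
  set.seed(64)
  yt <- rnorm(200, 120, 15); yp <- yt + rnorm(200, 1, 4)
  bb <- bland_altman(yt, yp)
  d <- yp - yt
  expect_equal(bb$mean_diff, mean(d))
  expect_equal(bb$sd_diff, sqrt(mean((d - mean(d))^2)))
  expect_true(bb$frac_within >= 0.9)
  expect_true(all(abs((bb$loa_upper + bb$loa_lower) / 2 - bb$mean_diff) < 1e-12))
})

test_that("evaluate_bp aggregates a perfect predictor into all-pass verdicts", {
  set.seed(65)
  # 90 distinct records so the AAMI subject-count requirement can be met
  segments <- tibble::tibble(
    record_id = sprintf("r%03d", 1:90),
    offset = 0L,
    ppg = replicate(90, rnorm(32), simplify = FALSE),
    abp = replicate(90, 100 + 25 * sin(1:32 / 3) + rnorm(32, 0, 5),
                    simplify = FALSE)
  )
  segments$pred_abp <- segments$abp
  ev <- evaluate_bp(segments)
  expect_s3_class(ev, "bp_evaluation")
  expect_equal(ev$parameters$bhs_grade, c("A", "A", "A"))
  expect_true(all(ev$parameters$aami_pass))
  expect_equal(ev$parameters$mae, rep(0, 3))
  expect_equal(ev$waveform$mae, 0)
  expect_equal(ev$waveform$r2, 1)
  expect_equal(tidy(ev), ev$parameters)
  gl <- glance(ev)
  expect_equal(gl$worst_bhs_grade, "A")
  expect_true(gl$aami_all_pass)
  # misaligned predictions are rejected
  bad <- segments
  bad$pred_abp[[1]] <- rnorm(16)
  expect_error(evaluate_bp(bad), "misaligned")
})

test_that("evaluation reports round-trip through JSON serialization", {
  set.seed(66)
  segments <- tibble::tibble(
    record_id = rep(c("a", "b"), each = 3), offset = rep(c(0L, 32L, 64L), 2),
    ppg = replicate(6, rnorm(32), simplify = FALSE),
    abp = replicate(6, rnorm(1, 100, 8) + 20 * sin(1:32 / 4) + rnorm(32),
                    simplify = FALSE)
  )
  segments$pred_abp <- lapply(segments$abp, function(a) a + rnorm(32, 0, 3))
  ev <- evaluate_bp(segments)
  dir <- tempfile()
  write_evaluation(ev, dir)
  expect_true(file.exists(file.path(dir, "report.json")))
  expect_true(file.exists(file.path(dir, "metrics.csv")))
  back <- read_evaluation(dir)
  expect_equal(back$parameters$mae, ev$parameters$mae, tolerance = 1e-12)
  expect_equal(back$parameters$bhs_grade, ev$parameters$bhs_grade)
  expect_equal(back$waveform$mae, ev$waveform$mae, tolerance = 1e-12)
  expect_equal(back$n_segments, ev$n_segments)
  unlink(dir, recursive = TRUE)
})

test_that("evaluation plots build for each report type", {
  set.seed(67)
  segments <- tibble::tibble(
    record_id = sprintf("r%02d", 1:20), offset = 0L,
    ppg = replicate(20, rnorm(32), simplify = FALSE),
    abp = replicate(20, 100 + 20 * sin(1:32 / 4) + rnorm(32), simplify = FALSE)
  )
  segments$pred_abp <- lapply(segments$abp, function(a) a + rnorm(32, 0, 2))
  ev <- evaluate_bp(segments)
  for (type in c("bland_altman", "error_hist", "regression")) {
    expect_s3_class(autoplot(ev, type = type, parameter = "sbp"), "ggplot")
  }
})
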