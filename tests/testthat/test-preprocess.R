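# Record filtering, spectral baseline removal, zero-phase bandpass, peak
# clipping, z-scoring, segmentation and splitting.

test_that("record filtering keeps the inclusive duration boundary", {
  rs <- bp_record_set(list(
    bp_record("short", rnorm(400 * 125), rnorm(400 * 125)),   # 400 s
    bp_record("exact", rnorm(480 * 125), rnorm(480 * 125)),   # 480 s
    bp_record("long", rnorm(500 * 125), rnorm(500 * 125))
  ))
  suppressMessages(kept <- filter_records(rs, 480))
  expect_equal(kept$record_id, c("exact", "long"))
  suppressMessages(empty <- filter_records(kept[0, ], 480))
  expect_equal(nrow(empty), 0L)
})

test_that("spectral baseline removal cancels drift and preserves in-band tones", {
  fs <- 125
  t <- (0:(fs * 30 - 1)) / fs
  # constant input is pure DC: removed entirely
  expect_equal(remove_baseline_fft(rep(3.7, 500), fs), rep(0, 500),
               tolerance = 1e-10)
  # 1 Hz sine on a linear ramp: drift removed, tone kept
  tone <- sin(2 * pi * 1 * t)
  y <- remove_baseline_fft(tone + 0.5 * t, fs)
  expect_gt(stats::cor(y, tone), 0.99)
  expect_lt(abs(mean(y)), 1e-8)
  # pure 2 Hz tone: RMS change < 1 %
  tone2 <- sin(2 * pi * 2 * t)
  y2 <- remove_baseline_fft(tone2, fs)
  expect_lt(abs(sqrt(mean(y2^2)) / sqrt(mean(tone2^2)) - 1), 0.01)
  expect_error(remove_baseline_fft(c(1, NA, 3), fs), "non-finite")
})

test_that("bandpass is zero-phase with the specified stopband suppression", {
  fs <- 125
  t <- (0:(fs * 60 - 1)) / fs
  power <- function(x) mean(x^2)
  # stopband tones: > 95 % power suppression
  for (f0 in c(0.05, 30)) {
    x <- sin(2 * pi * f0 * t)
    y <- bandpass_butterworth(x, fs, 0.5, 8, 4)
    expect_lt(power(y) / power(x), 0.05)
  }
  # 2 Hz passband tone: amplitude within 5 %, peak cross-correlation at lag 0
  x2 <- sin(2 * pi * 2 * t)
  y2 <- bandpass_butterworth(x2, fs, 0.5, 8, 4)
  mid <- seq(fs * 5, fs * 55)              # away from the record edges
  expect_lt(abs(max(y2[mid]) / max(x2[mid]) - 1), 0.05)
  cc <- stats::ccf(y2[mid], x2[mid], lag.max = 20, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # linearity / trivial input
  expect_equal(bandpass_butterworth(rep(0, 1000), fs), rep(0, 1000))
  expect_error(bandpass_butterworth(rnorm(10), fs), "too short")
})

test_that("peak clipping bounds the signal by mean +/- k sd and interpolates", {
  set.seed(5)
  x <- rnorm(2000)
  xs <- x
  xs[700] <- 10                             # +10 sigma spike
  y <- clip_peaks(xs, k = 3)
  m <- mean(xs); s <- sqrt(mean((xs - m)^2))
  expect_lte(max(y), m + 3 * s)
  expect_gte(min(y), m - 3 * s)
  expect_false(y[700] == 10)
  flagged <- abs(xs - m) > 3 * s
  expect_equal(y[!flagged], xs[!flagged])   # unflagged samples untouched
  # signal entirely within threshold: unchanged
  z <- sin(1:100 / 5)
  expect_identical(clip_peaks(z, 3), z)
  # constant signal: zero variance convention, unchanged
  expect_identical(clip_peaks(rep(2, 10), 3), rep(2, 10))
  # flagged run at the edge is filled by nearest-valid extension
  xe <- c(50, 50, rnorm(100))
  ye <- clip_peaks(xe, 2)
  expect_equal(ye[1], ye[3])
  # everything flagged: degenerate
  expect_error(clip_peaks(c(0, 0, 10), k = 0.5), "degenerate")
})

test_that("z-score uses the population convention and is invertible", {
  z <- zscore_signal(c(1, 2, 3))
  expect_equal(z$mu, 2)
  expect_equal(z$sigma, sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(z$z, c(-1.2247, 0, 1.2247), tolerance = 1e-4)
  set.seed(6)
  x <- rnorm(5000, 7, 3)
  out <- zscore_signal(x)
  expect_lt(abs(mean(out$z)), 1e-9)
  expect_lt(abs(sqrt(mean((out$z - mean(out$z))^2)) - 1), 1e-6)
  expect_equal(out$z * out$sigma + out$mu, x)    # inversion
  zz <- zscore_signal(out$z)                     # idempotence
  expect_equal(zz$z, out$z, tolerance = 1e-9)
  expect_error(zscore_signal(rep(1, 10)), "zero-variance")
})

test_that("segmentation drops the trailing remainder and records offsets", {
  x <- rnorm(2500); y <- rnorm(2500)
  seg <- segment_signals(x, y, 1024, record_id = "r")
  expect_equal(nrow(seg), 2L)
  expect_equal(seg$offset, c(0L, 1024L))
  expect_equal(seg$ppg[[2]], x[1025:2048])
  expect_equal(nrow(segment_signals(rnorm(1024), rnorm(1024), 1024)), 1L)
  expect_equal(nrow(segment_signals(rnorm(1000), rnorm(1000), 1024)), 0L)
})

test_that("splitting is an exact seeded partition with 6:2:2 apportionment", {
  seg <- tibble::tibble(record_id = "r", offset = seq_len(100),
                        ppg = replicate(100, rnorm(4), simplify = FALSE),
                        abp = replicate(100, rnorm(4), simplify = FALSE))
  s1 <- split_segments(seg, c(6, 2, 2), seed = 11)
  expect_equal(as.integer(table(s1$split)[c("train", "val", "test")]),
               c(60L, 20L, 20L))
  s2 <- split_segments(seg, c(6, 2, 2), seed = 11)
  expect_identical(s1$split, s2$split)          # determinism
  s3 <- split_segments(seg, c(6, 2, 2), seed = 12)
  expect_false(identical(s1$split, s3$split))
  # partition: disjoint and exhaustive by construction of the labels
  expect_true(all(s1$split %in% c("train", "val", "test")))
  # odd sizes follow largest remainder
  s4 <- split_segments(seg[1:7, ], c(6, 2, 2), seed = 1)
  expect_equal(sum(s4$split == "train"), 4L)
  expect_warning(split_segments(seg[1:2, ], c(6, 2, 2), 1), "fewer than 3")
})

test_that("the full chain preserves length per record and per-beat ABP extrema", {
  ds <- synth_dataset(clean_synth_config(n_records = 3, duration_s = 120,
                                         seed = 11))
  seg <- suppressMessages(preprocess_records(
    ds$records, preprocess_config(min_duration_s = 60, seed = 1)))
  # each 120 s record at 125 Hz gives floor(15000/1024) = 14 segments
  expect_equal(nrow(seg), 3L * 14L)
  expect_true(all(lengths(seg$ppg) == 1024))
  expect_true(all(lengths(seg$abp) == 1024))
  # per-beat extrema of the preprocessed ABP stay within 2 mmHg of the drawn
  # ground truth (ABP receives only the low-pass branch by default)
  gt <- ds$ground_truth
  worst <- 0
  for (rid in unique(gt$record_id)) {
    g <- gt[gt$record_id == rid, ]
    ss <- seg[seg$record_id == rid, ]
    abp <- unlist(ss$abp[order(ss$offset)])
    for (i in seq_len(nrow(g) - 1L)) {
      if (g$onset[i + 1] > length(abp)) break
      beat <- abp[(g$onset[i] + 1):g$onset[i + 1]]
      worst <- max(worst, abs(max(beat) - g$sbp[i]), abs(min(beat) - g$dbp[i]))
    }
  }
  expect_lt(worst, 2)
  # stored normalization allows inversion to mmHg
  expect_true(all(seg$norm_sigma > 0))
})
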