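#' Preprocessing configuration
#'
#' Parameters of the record-to-segment pipeline: record filtering, spectral
#' baseline removal, zero-phase Butterworth bandpass, peak clipping, z-score
#' standardization, windowing and splitting.
#'
#' @param min_duration_s Minimum record duration kept, seconds (default 480;
#'   the boundary is inclusive).
#' @param band_low,band_high Bandpass corner frequencies in Hz (0.5 and 8).
#' @param butter_order Butterworth order (4).
#' @param baseline_cutoff_hz Baseline-removal high-pass cutoff in Hz (0.5).
#' @param clip_k Peak-clipping threshold multiplier in standard deviations (3).
#' @param window_len Segment length in samples (1024).
#' @param split_ratios Train/validation/test ratios (6:2:2).
#' @param seed Seed for the split shuffle.
#' @param zscore_abp If `TRUE` (default) the training-set global ABP mean/sd
#'   are recorded with each segment so model targets can be standardized and
#'   predictions inverted back to mmHg.
#' @param abp_mode `"lowpass"` (default) applies only the high-corner low-pass
#'   to ABP, preserving its absolute pressure level; `"bandpass"` applies the
#'   full 0.5-8 Hz bandpass to ABP as well.
#' @return A list of class `ppgbp_preprocess_config`.
#' @export
preprocess_config <- function(min_duration_s = 480, band_low = 0.5,
                              band_high = 8, butter_order = 4,
                              baseline_cutoff_hz = 0.5, clip_k = 3,
                              window_len = 1024, split_ratios = c(6, 2, 2),
                              seed = 1L, zscore_abp = TRUE,
                              abp_mode = c("lowpass", "bandpass")) {
  abp_mode <- match.arg(abp_mode)
  stopifnot(band_low > 0, band_low < band_high, butter_order >= 1,
            clip_k > 0, window_len >= 2, all(split_ratios > 0))
  structure(list(
    min_duration_s = min_duration_s, band_low = band_low,
    band_high = band_high, butter_order = butter_order,
    baseline_cutoff_hz = baseline_cutoff_hz, clip_k = clip_k,
    window_len = as.integer(window_len), split_ratios = split_ratios,
    seed = as.integer(seed), zscore_abp = zscore_abp, abp_mode = abp_mode
  ), class = "ppgbp_preprocess_config")
}

#' Drop records shorter than a duration threshold
#'
#' @param record_set Record-set tibble.
#' @param min_duration_s Threshold in seconds; records with
#'   `duration_s >= min_duration_s` are kept (inclusive boundary).
#' @return The filtered record set. Counts before/after are reported via
#'   `message()`.
#' @export
filter_records <- function(record_set, min_duration_s = 480) {
  n0 <- nrow(record_set)
  out <- dplyr::filter(record_set, .data$duration_s >= min_duration_s)
  message("filter_records: kept ", nrow(out), " of ", n0,
          " records (>= ", min_duration_s, " s)")
  out
}

#' Remove baseline drift with a spectral high-pass
#'
#' Computes the FFT of the signal, zeroes all bins below `cutoff_hz`
#' (including DC) and ramps the gain from 0 to 1 over a raised-cosine
#' transition band of width `taper_hz` above the cutoff to avoid ringing,
#' then inverts the transform. The signal is mirrored (even extension)
#' before the transform so that aperiodic drift such as a linear ramp stays
#' confined to low frequencies instead of leaking across the spectrum.
#'
#' @param x Numeric signal (all finite).
#' @param fs Sampling rate in Hz.
#' @param cutoff_hz Cutoff below which content is removed (default 0.5 Hz).
#' @param taper_hz Width of the raised-cosine transition band (default 0.1 Hz).
#' @return Filtered signal of the same length, (near-)zero mean.
#' @export
remove_baseline_fft <- function(x, fs, cutoff_hz = 0.5, taper_hz = 0.1) {
  if (!all(is.finite(x))) stop("signal contains non-finite samples", call. = FALSE)
  n0 <- length(x)
  if (n0 < 2L) stop("signal must have at least 2 samples", call. = FALSE)
  xe <- c(x, rev(x))                    # even extension, continuous at ends
  n <- length(xe)
  k <- 0:(n - 1L)
  f <- pmin(k, n - k) * fs / n          # two-sided frequency magnitude
  gain <- numeric(n)
  gain[f >= cutoff_hz + taper_hz] <- 1
  ramp <- f > cutoff_hz & f < cutoff_hz + taper_hz
  gain[ramp] <- 0.5 * (1 - cos(pi * (f[ramp] - cutoff_hz) / taper_hz))
  y <- Re(stats::fft(stats::fft(xe) * gain, inverse = TRUE)) / n
  y[seq_len(n0)]
}

#' Zero-phase Butterworth bandpass filter
#'
#' Designs a Butterworth bandpass with [signal::butter()] and applies it
#' forward and backward (zero phase). The signal is extended by odd
#' reflection at both ends before filtering so that the filter transient does
#' not distort the edges.
#'
#' @param x Numeric signal.
#' @param fs Sampling rate in Hz.
#' @param low,high Corner frequencies in Hz.
#' @param order Filter order (default 4).
#' @param type `"pass"` (default) or `"low"` (only the high corner is used).
#' @return Filtered signal, same length; passband tones keep their amplitude
#'   and phase, stopband tones are suppressed.
#' @export
bandpass_butterworth <- function(x, fs, low = 0.5, high = 8, order = 4,
                                 type = c("pass", "low")) {
  type <- match.arg(type)
  n <- length(x)
  min_len <- 3L * (2L * order + 1L)
  if (n <= min_len) {
    stop("signal too short (", n, " samples) for order-", order,
         " zero-phase filtering; need > ", min_len, call. = FALSE)
  }
  bf <- if (type == "pass") {
    signal::butter(order, c(low, high) / (fs / 2), type = "pass")
  } else {
    signal::butter(order, high / (fs / 2), type = "low")
  }
  # odd reflection padding, capped by signal length
  npad <- min(n - 1L, as.integer(round(3 * fs / low)))
  head_pad <- 2 * x[1L] - x[(npad + 1L):2L]
  tail_pad <- 2 * x[n] - x[(n - 1L):(n - npad)]
  ext <- c(head_pad, x, tail_pad)
  y <- signal::filtfilt(bf, ext)
  y[(npad + 1L):(npad + n)]
}

#' Clip abnormal peaks by threshold and linear interpolation
#'
#' Samples whose deviation from the signal mean exceeds `k` standard
#' deviations are flagged and replaced by linear interpolation between the
#' nearest unflagged neighbours; flagged runs touching the sequence edges are
#' filled with the nearest valid value. Mean and standard deviation are those
#' of the input (population convention).
#'
#' @param x Numeric signal (length >= 3).
#' @param k Threshold multiplier (default 3).
#' @return The clipped signal; its range is bounded by `mean(x) +/- k*sd`.
#' @export
clip_peaks <- function(x, k = 3) {
  n <- length(x)
  if (n < 3L) stop("need at least 3 samples", call. = FALSE)
  m <- mean(x)
  s <- sqrt(mean((x - m)^2))
  if (s == 0) return(x)                 # constant signal: nothing exceeds
  flagged <- abs(x - m) > k * s
  if (!any(flagged)) return(x)
  if (all(flagged)) stop("all samples exceed the clipping threshold; degenerate signal",
                         call. = FALSE)
  ok <- which(!flagged)
  x[flagged] <- stats::approx(ok, x[ok], xout = which(flagged), rule = 2)$y
  x
}

#' Z-score standardization
#'
#' Standardizes a signal to zero mean and unit standard deviation using the
#' population convention, returning the transform parameters for inversion.
#'
#' @param x Numeric signal with positive variance.
#' @return List with `z` (standardized signal), `mu` and `sigma`.
#' @export
#' @examples
#' zscore_signal(c(1, 2, 3))  # z = (-1.2247, 0, 1.2247)
zscore_signal <- function(x) {
  mu <- mean(x)
  sigma <- sqrt(mean((x - mu)^2))
  if (!is.finite(sigma) || sigma <= 0) {
    stop("zero-variance signal cannot be z-scored", call. = FALSE)
  }
  list(z = (x - mu) / sigma, mu = mu, sigma = sigma)
}

#' Cut a record into non-overlapping fixed-length segment pairs
#'
#' @param ppg,abp Equal-length numeric vectors.
#' @param window_len Samples per segment (default 1024).
#' @param record_id Provenance id stored with each segment.
#' @return Segment tibble with `floor(length/window_len)` rows and 0-based
#'   `offset`s; the trailing remainder is dropped.
#' @export
segment_signals <- function(ppg, abp, window_len = 1024, record_id = "") {
  stopifnot(length(ppg) == length(abp))
  n_win <- length(ppg) %/% window_len
  offsets <- (seq_len(n_win) - 1L) * window_len
  tibble::tibble(
    record_id = rep(record_id, n_win),
    offset = offsets,
    ppg = lapply(offsets, function(o) ppg[(o + 1L):(o + window_len)]),
    abp = lapply(offsets, function(o) abp[(o + 1L):(o + window_len)])
  )
}

# internal: largest-remainder apportionment of n into parts ~ ratios
apportion <- function(n, ratios) {
  q <- n * ratios / sum(ratios)
  base <- floor(q)
  rem <- n - sum(base)
  if (rem > 0) {
    extra <- order(q - base, decreasing = TRUE)[seq_len(rem)]
    base[extra] <- base[extra] + 1
  }
  as.integer(base)
}

#' Randomly split segments into train/validation/test sets
#'
#' Segment-level uniform random partition by a seeded shuffle. Sizes follow
#' largest-remainder apportionment of the ratios, so 100 segments at 6:2:2
#' give exactly 60/20/20. The same seed always yields the same membership.
#'
#' @param segments Segment tibble.
#' @param ratios Positive split ratios (train, val, test); default `c(6, 2, 2)`.
#' @param seed Integer seed for the shuffle.
#' @return The segment tibble with a `split` column.
#' @export
split_segments <- function(segments, ratios = c(6, 2, 2), seed = 1L) {
  stopifnot(all(ratios > 0), length(ratios) == 3L)
  n <- nrow(segments)
  if (n < 3L) {
    warning("fewer than 3 segments; assigning all to the training set",
            call. = FALSE)
    segments$split <- rep("train", n)
    return(segments)
  }
  sizes <- apportion(n, ratios)
  perm <- withr::with_seed(seed, sample.int(n))
  split <- character(n)
  split[perm[seq_len(sizes[1])]] <- "train"
  split[perm[sizes[1] + seq_len(sizes[2])]] <- "val"
  split[perm[sizes[1] + sizes[2] + seq_len(sizes[3])]] <- "test"
  segments$split <- split
  segments
}

#' Run the full record-to-segment preprocessing chain
#'
#' Applies, in order: duration filtering; per-record PPG baseline removal,
#' bandpass filtering, peak clipping and z-scoring; ABP low-pass (or full
#' bandpass, see [preprocess_config()]) and peak clipping; windowing into
#' fixed-length segment pairs; and the seeded train/val/test split. ABP stays
#' in mmHg; the training-set global ABP mean/sd are attached to every segment
#' (`norm_mu`, `norm_sigma`) for target standardization and inversion.
#'
#' @param record_set Record-set tibble.
#' @param config A [preprocess_config()].
#' @return Segment tibble with columns `record_id`, `offset`, `ppg`
#'   (standardized), `abp` (mmHg), `split`, `norm_mu`, `norm_sigma`.
#' @export
preprocess_records <- function(record_set, config = preprocess_config()) {
  stopifnot(inherits(config, "ppgbp_preprocess_config"))
  kept <- filter_records(record_set, config$min_duration_s)
  seg_list <- purrr::pmap(
    list(kept$record_id, kept$ppg, kept$abp, kept$fs),
    function(id, ppg, abp, fs) {
      ppg <- remove_baseline_fft(ppg, fs, config$baseline_cutoff_hz)
      ppg <- bandpass_butterworth(ppg, fs, config$band_low, config$band_high,
                                  config$butter_order, type = "pass")
      ppg <- clip_peaks(ppg, config$clip_k)
      ppg <- zscore_signal(ppg)$z
      abp_type <- if (config$abp_mode == "bandpass") "pass" else "low"
      abp <- bandpass_butterworth(abp, fs, config$band_low, config$band_high,
                                  config$butter_order, type = abp_type)
      abp <- clip_peaks(abp, config$clip_k)
      segment_signals(ppg, abp, config$window_len, record_id = id)
    }
  )
  segments <- dplyr::bind_rows(seg_list)
  if (!nrow(segments)) {
    segments$split <- character(0)
    segments$norm_mu <- double(0)
    segments$norm_sigma <- double(0)
    return(segments)
  }
  segments <- split_segments(segments, config$split_ratios, config$seed)
  if (config$zscore_abp) {
    train_abp <- unlist(segments$abp[segments$split == "train"])
    if (!length(train_abp)) train_abp <- unlist(segments$abp)
    mu <- mean(train_abp)
    sigma <- sqrt(mean((train_abp - mu)^2))
    if (sigma <= 0) sigma <- 1
  } else {
    mu <- 0; sigma <- 1
  }
  segments$norm_mu <- rep(mu, nrow(segments))
  segments$norm_sigma <- rep(sigma, nrow(segments))
  segments
}
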