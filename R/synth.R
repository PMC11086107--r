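#' Synthetic paired PPG/ABP generator configuration
#'
#' The generator builds an arterial pressure waveform beat by beat. Each
#' record draws an operating point (SBP, DBP) uniformly from the configured
#' ranges (redrawn while the pair is not a plausible pulse); each beat then
#' jitters that point by up to `beat_jitter_mmHg` (clipped to the ranges),
#' sets the diastolic baseline to the drawn DBP and adds a two-Gaussian
#' pulse (systolic peak plus a delayed dicrotic wave) whose maximum reaches
#' the drawn SBP exactly before corruption. The PPG channel is a
#' fixed monotone warp of the (delayed) pressure waveform, so the PPG-to-ABP
#' mapping is deterministic and learnable; baseline drift, spike artifacts
#' and additive noise are then applied to the PPG, and small additive noise
#' to the ABP. Ground-truth per-beat SBP/DBP/MBP are recorded pre-corruption.
#'
#' Default SBP/DBP ranges span the post-preprocessing pressure ranges of the
#' UCI cuff-less BP corpus (SBP roughly 86-179 mmHg, DBP 58-134 mmHg). Beats
#' where the drawn DBP is not below the drawn SBP are redrawn.
#'
#' @param n_records Number of records to generate.
#' @param duration_s Duration of each record in seconds.
#' @param fs Sampling rate in Hz (125).
#' @param hr_bpm Heart-rate range (per record, uniform draw; per-beat jitter
#'   of about 3% is added).
#' @param sbp_mmHg,dbp_mmHg Uniform draw ranges in mmHg for the record
#'   operating point.
#' @param beat_jitter_mmHg Half-width of the per-beat uniform jitter around
#'   the record operating point (mmHg).
#' @param sys_width_s Systolic Gaussian width (s).
#' @param dicrotic_amp Dicrotic wave amplitude relative to the systolic peak.
#' @param dicrotic_delay_s Dicrotic wave delay after the systolic peak (s).
#' @param drift_amp PPG baseline-drift amplitude (a.u.).
#' @param spike_rate Expected PPG spike artifacts per minute.
#' @param spike_amp Spike amplitude (a.u.).
#' @param noise_sd PPG additive white-noise standard deviation (a.u.).
#' @param abp_noise_sd ABP additive noise standard deviation (mmHg).
#' @param delay_s PPG delay relative to ABP (s; default 0.04).
#' @param warp_gamma Exponent of the monotone PPG warp. The curvature of the
#'   warp is what keeps the absolute pressure level identifiable after PPG
#'   records are standardized per record: under a near-affine warp the level
#'   would be lost with the record mean/scale and the regression task would
#'   be ill-posed.
#' @param seed Master seed; each record uses an independent substream.
#' @return A list of class `ppgbp_synth_config`.
#' @export
synth_config <- function(n_records = 10L, duration_s = 120, fs = 125,
                         hr_bpm = c(55, 100), sbp_mmHg = c(86, 179),
                         dbp_mmHg = c(58, 134), beat_jitter_mmHg = 4,
                         sys_width_s = 0.055,
                         dicrotic_amp = 0.25, dicrotic_delay_s = 0.25,
                         drift_amp = 0.3, spike_rate = 2, spike_amp = 4,
                         noise_sd = 0.05, abp_noise_sd = 0.5,
                         delay_s = 0.04, warp_gamma = 2.5, seed = 1L) {
  stopifnot(fs > 16, duration_s > 0, n_records >= 1,
            diff(hr_bpm) >= 0, diff(sbp_mmHg) > 0, diff(dbp_mmHg) > 0)
  structure(list(
    n_records = as.integer(n_records), duration_s = duration_s, fs = fs,
    hr_bpm = hr_bpm, sbp_mmHg = sbp_mmHg, dbp_mmHg = dbp_mmHg,
    beat_jitter_mmHg = beat_jitter_mmHg,
    sys_width_s = sys_width_s, dicrotic_amp = dicrotic_amp,
    dicrotic_delay_s = dicrotic_delay_s, drift_amp = drift_amp,
    spike_rate = spike_rate, spike_amp = spike_amp, noise_sd = noise_sd,
    abp_noise_sd = abp_noise_sd, delay_s = delay_s,
    warp_gamma = warp_gamma, seed = as.integer(seed)
  ), class = "ppgbp_synth_config")
}

# internal: two-Gaussian pulse at sample times t (s), affinely normalized to
# span exactly [0, 1] over the sampled beat so the drawn DBP and SBP are hit
# exactly at one sample each.
pulse_shape <- function(t, period_s, cfg) {
  scale <- max(1, period_s / 0.8)       # stretch timing for slow beats
  m1 <- 0.13 * scale
  s1 <- cfg$sys_width_s * scale
  m2 <- m1 + cfg$dicrotic_delay_s
  s2 <- 2 * s1
  p <- exp(-((t - m1)^2) / (2 * s1^2)) +
       cfg$dicrotic_amp * exp(-((t - m2)^2) / (2 * s2^2))
  (p - min(p)) / (max(p) - min(p))
}

# internal: draw a record-level (sbp, dbp) pair, redrawing while the pair is
# not a plausible pulse (DBP must sit at least `margin` below SBP)
draw_record_bp <- function(cfg, margin = 20) {
  for (i in 1:100) {
    sbp <- stats::runif(1, cfg$sbp_mmHg[1], cfg$sbp_mmHg[2])
    dbp <- stats::runif(1, cfg$dbp_mmHg[1], cfg$dbp_mmHg[2])
    if (dbp < sbp - margin) return(c(sbp = sbp, dbp = dbp))
  }
  stop("could not draw DBP < SBP in 100 attempts; infeasible ranges",
       call. = FALSE)
}

#' Generate one synthetic record with per-beat ground truth
#'
#' @param cfg A [synth_config()].
#' @param record_idx Index used for the record id and the RNG substream.
#' @return List with `record` (one-row record-set tibble) and `ground_truth`
#'   (tibble: `record_id`, `beat_idx`, `onset` 0-based sample, `sbp`, `dbp`,
#'   `mbp` in mmHg; only beats that fit entirely in the record are listed).
#' @export
synth_record <- function(cfg = synth_config(), record_idx = 1L) {
  withr::with_seed(cfg$seed + 7919L * as.integer(record_idx), {
    fs <- cfg$fs
    n <- as.integer(round(cfg$duration_s * fs))
    hr <- stats::runif(1, cfg$hr_bpm[1], cfg$hr_bpm[2])
    bp0 <- draw_record_bp(cfg)      # record-level operating point
    jit <- cfg$beat_jitter_mmHg
    # slow sinusoidal within-record BP variation (vasomotor-type drift) so
    # consecutive diastolic baselines differ by ~1 mmHg, never by a step
    f_s <- stats::runif(1, 0.02, 0.08); ph_s <- stats::runif(1, 0, 2 * pi)
    f_d <- stats::runif(1, 0.02, 0.08); ph_d <- stats::runif(1, 0, 2 * pi)
    abp <- numeric(n)
    onsets <- integer(0); sbps <- double(0); dbps <- double(0)
    pos <- 0L
    while (TRUE) {
      period_s <- 60 / (hr * stats::runif(1, 0.97, 1.03))
      blen <- max(2L, as.integer(round(period_s * fs)))
      if (pos + blen > n) break
      t0 <- pos / fs
      sbp <- min(max(bp0[["sbp"]] + jit * sin(2 * pi * f_s * t0 + ph_s) +
                       stats::runif(1, -0.5, 0.5),
                     cfg$sbp_mmHg[1]), cfg$sbp_mmHg[2])
      dbp <- min(max(bp0[["dbp"]] + jit * sin(2 * pi * f_d * t0 + ph_d) +
                       stats::runif(1, -0.5, 0.5),
                     cfg$dbp_mmHg[1]), cfg$dbp_mmHg[2])
      t <- (seq_len(blen) - 1L) / fs
      p <- pulse_shape(t, period_s, cfg)
      abp[(pos + 1L):(pos + blen)] <- dbp + (sbp - dbp) * p
      onsets <- c(onsets, pos)
      sbps <- c(sbps, sbp); dbps <- c(dbps, dbp)
      pos <- pos + blen
    }
    if (pos < n) abp[(pos + 1L):n] <- if (pos > 0L) abp[pos] else mean(cfg$dbp_mmHg)

    # PPG: monotone warp of the delayed clean pressure waveform
    d <- as.integer(round(cfg$delay_s * fs))
    abp_delayed <- c(rep(abp[1L], d), abp)[seq_len(n)]
    u <- pmin(pmax((abp_delayed - 50) / 150, 1e-3), 1)
    ppg <- u^cfg$warp_gamma

    tt <- (seq_len(n) - 1L) / fs
    if (cfg$drift_amp > 0) {
      ppg <- ppg + cfg$drift_amp *
        sin(2 * pi * stats::runif(1, 0.05, 0.3) * tt + stats::runif(1, 0, 2 * pi))
    }
    n_spikes <- stats::rpois(1, cfg$spike_rate * cfg$duration_s / 60)
    if (n_spikes > 0 && cfg$spike_amp > 0) {
      at <- sample.int(n, n_spikes)
      for (s in at) {
        w <- s:min(n, s + 4L)
        ppg[w] <- ppg[w] + sample(c(-1, 1), 1) * cfg$spike_amp *
          exp(-(seq_along(w) - 1))
      }
    }
    if (cfg$noise_sd > 0) ppg <- ppg + stats::rnorm(n, 0, cfg$noise_sd)
    if (cfg$abp_noise_sd > 0) abp <- abp + stats::rnorm(n, 0, cfg$abp_noise_sd)

    id <- sprintf("synth-%04d", as.integer(record_idx))
    list(
      record = bp_record_set(bp_record(id, ppg = ppg, abp = abp, fs = fs),
                             source = "synthetic"),
      ground_truth = tibble::tibble(
        record_id = rep(id, length(onsets)),
        beat_idx = seq_along(onsets),
        onset = onsets,
        sbp = sbps, dbp = dbps, mbp = (sbps + 2 * dbps) / 3
      )
    )
  })
}

#' Generate a synthetic dataset of paired PPG/ABP records
#'
#' Applies [synth_record()] `n_records` times with independent seeded
#' substreams.
#'
#' @param cfg A [synth_config()].
#' @return List with `records` (record-set tibble) and `ground_truth`
#'   (per-beat tibble across all records).
#' @export
synth_dataset <- function(cfg = synth_config()) {
  out <- lapply(seq_len(cfg$n_records), function(i) synth_record(cfg, i))
  list(
    records = bp_record_set(dplyr::bind_rows(lapply(out, `[[`, "record")),
                            source = "synthetic"),
    ground_truth = dplyr::bind_rows(lapply(out, `[[`, "ground_truth"))
  )
}
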