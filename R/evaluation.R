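#' Extract blood-pressure parameters from a pressure waveform
#'
#' Systolic pressure is the waveform maximum, diastolic the minimum, and
#' mean pressure the standard one-third/two-thirds combination
#' `MBP = (SBP + 2 DBP) / 3`.
#'
#' @param waveform Numeric vector in mmHg (finite, non-empty).
#' @return One-row tibble with `sbp`, `dbp`, `mbp`.
#' @export
#' @examples
#' extract_bp(c(80, 95, 120, 100, 85))  # sbp 120, dbp 80, mbp 93.33
extract_bp <- function(waveform) {
  if (!length(waveform) || !all(is.finite(waveform))) {
    stop("waveform must be non-empty and finite", call. = FALSE)
  }
  sbp <- max(waveform); dbp <- min(waveform)
  tibble::tibble(sbp = sbp, dbp = dbp, mbp = (sbp + 2 * dbp) / 3)
}

#' Error metrics between true and predicted values
#'
#' Computes mean error (ME), mean absolute error (MAE), mean squared error
#' (MSE), `std_eq20 = sqrt(MSE)` (the root-mean-square error, reported here
#' under the name it is usually printed with in BP-prediction tables),
#' the conventional dispersion `sd_diff` of the errors about their own mean
#' (population convention, as used for Bland-Altman and AAMI), the
#' coefficient of determination R-squared, and the Pearson correlation `r`
#' computed from its raw-moment form.
#'
#' @param y_true,y_pred Equal-length numeric vectors (length >= 2).
#' @return One-row tibble: `me`, `mae`, `mse`, `std_eq20`, `sd_diff`, `r2`,
#'   `r`, `n`. Errors are `y_true - y_pred`. With zero variance in `y_true`,
#'   `r2` and `r` are `NA` with a warning.
#' @export
bp_metrics <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2L)
  n <- length(y_true)
  e <- y_true - y_pred
  me <- mean(e)
  mae <- mean(abs(e))
  mse <- mean(e^2)
  sd_diff <- sqrt(mean((e - me)^2))
  if (stats::var(y_true) == 0) {
    warning("zero variance in y_true: R-squared and r are undefined",
            call. = FALSE)
    r2 <- NA_real_; r <- NA_real_
  } else {
    r2 <- 1 - sum(e^2) / sum((y_true - mean(y_true))^2)
    r <- (n * sum(y_true * y_pred) - sum(y_true) * sum(y_pred)) /
      (sqrt(n * sum(y_true^2) - sum(y_true)^2) *
       sqrt(n * sum(y_pred^2) - sum(y_pred)^2))
  }
  tibble::tibble(me = me, mae = mae, mse = mse, std_eq20 = sqrt(mse),
                 sd_diff = sd_diff, r2 = r2, r = r, n = n)
}

# BHS grade thresholds: minimum percentage of absolute errors within
# 5 / 10 / 15 mmHg for each grade
bhs_thresholds <- function() {
  list(A = c(60, 85, 95), B = c(50, 75, 90), C = c(40, 65, 85))
}

#' Grade prediction errors against the BHS standard
#'
#' The percentage of absolute errors within 5, 10 and 15 mmHg (inclusive) is
#' computed; each threshold is graded A/B/C by the highest grade whose
#' minimum percentage is met (inclusive), D if even grade C fails; the
#' overall grade is the worst of the three per-threshold grades.
#'
#' Percentages are compared to the grade minima at one-decimal precision
#' (a `tol` of 0.05 percentage points): published BHS tables grade
#' e.g. 94.95% as meeting a 95% minimum while 89.88% does not meet 90%,
#' which is exactly comparison after rounding to one decimal.
#'
#' @param abs_errors Absolute errors in mmHg; alternatively supply `pct`.
#' @param pct Optional length-3 vector of precomputed percentages within
#'   5/10/15 mmHg (used instead of `abs_errors`).
#' @param tol Grading tolerance in percentage points (default 0.05,
#'   one-decimal precision; use 0 for strict comparison).
#' @return One-row tibble: `pct5`, `pct10`, `pct15`, `grade5`, `grade10`,
#'   `grade15`, `grade`.
#' @export
bhs_grade <- function(abs_errors = NULL, pct = NULL, tol = 0.05) {
  if (is.null(pct)) {
    if (!length(abs_errors)) stop("no errors supplied", call. = FALSE)
    abs_errors <- abs(abs_errors)
    pct <- vapply(c(5, 10, 15),
                  function(th) 100 * mean(abs_errors <= th), numeric(1))
  }
  stopifnot(length(pct) == 3L)
  th <- bhs_thresholds()
  grade_one <- function(i) {
    for (g in c("A", "B", "C")) if (pct[i] >= th[[g]][i] - tol) return(g)
    "D"
  }
  per <- vapply(1:3, grade_one, character(1))
  overall <- c("A", "B", "C", "D")[max(match(per, c("A", "B", "C", "D")))]
  tibble::tibble(pct5 = pct[1], pct10 = pct[2], pct15 = pct[3],
                 grade5 = per[1], grade10 = per[2], grade15 = per[3],
                 grade = overall)
}

#' Check compliance with the AAMI device criterion
#'
#' Requires mean error within 5 mmHg in magnitude, error standard deviation
#' within 8 mmHg, and at least 85 subjects. Boundaries are inclusive.
#'
#' @param me Mean error (mmHg).
#' @param sd_diff Standard deviation of the errors (mmHg).
#' @param n_subjects Number of subjects backing the evaluation.
#' @return One-row tibble: `me`, `sd_diff`, `n_subjects`, `pass`.
#' @export
aami_check <- function(me, sd_diff, n_subjects) {
  stopifnot(n_subjects >= 0)
  tibble::tibble(
    me = me, sd_diff = sd_diff, n_subjects = as.integer(n_subjects),
    pass = abs(me) <= 5 && sd_diff <= 8 && n_subjects >= 85
  )
}

#' Bland-Altman agreement analysis
#'
#' Differences are predicted minus true; the limits of agreement are the
#' mean difference plus/minus 1.96 times the standard deviation of the
#' differences (population convention).
#'
#' @param y_true,y_pred Equal-length numeric vectors (length >= 2).
#' @return One-row tibble: `mean_diff`, `sd_diff`, `loa_lower`, `loa_upper`,
#'   `frac_within` (fraction of differences inside the limits), `n`.
#' @export
bland_altman <- function(y_true, y_pred) {
  stopifnot(length(y_true) == length(y_pred), length(y_true) >= 2L)
  d <- y_pred - y_true
  mu <- mean(d)
  sigma <- sqrt(mean((d - mu)^2))
  lo <- mu - 1.96 * sigma; hi <- mu + 1.96 * sigma
  tibble::tibble(mean_diff = mu, sd_diff = sigma, loa_lower = lo,
                 loa_upper = hi, frac_within = mean(d >= lo & d <= hi),
                 n = length(d))
}

#' Full clinical evaluation of predicted ABP segments
#'
#' For every segment, SBP/DBP/MBP are extracted from both the predicted and
#' the true waveform ([extract_bp()]); the paired series per parameter are
#' then summarized with [bp_metrics()], graded with [bhs_grade()], checked
#' with [aami_check()] (using the number of distinct source records as the
#' subject count) and analyzed with [bland_altman()]. Waveform-level
#' (sample-by-sample) metrics are computed across all segments pooled.
#'
#' @param segments Segment tibble with list-columns `abp` (true, mmHg) and
#'   `pred_abp` (predicted, mmHg), e.g. from [predict.ppgbp_fit()].
#' @return Object of class `bp_evaluation`: list with `pairs` (per-segment
#'   true/predicted parameter values), `parameters` (per-parameter metrics +
#'   BHS + AAMI + Bland-Altman), `waveform` (pooled sample-level metrics),
#'   `n_segments`, `n_records`.
#' @export
evaluate_bp <- function(segments) {
  check_segments(segments, require_pred = TRUE)
  if (!nrow(segments)) stop("no segments to evaluate", call. = FALSE)
  if (any(lengths(segments$pred_abp) != lengths(segments$abp))) {
    stop("prediction/target lengths are misaligned", call. = FALSE)
  }
  true_bp <- dplyr::bind_rows(lapply(segments$abp, extract_bp))
  pred_bp <- dplyr::bind_rows(lapply(segments$pred_abp, extract_bp))
  pairs <- tibble::tibble(
    record_id = segments$record_id, offset = segments$offset,
    sbp_true = true_bp$sbp, sbp_pred = pred_bp$sbp,
    dbp_true = true_bp$dbp, dbp_pred = pred_bp$dbp,
    mbp_true = true_bp$mbp, mbp_pred = pred_bp$mbp
  )
  n_records <- length(unique(segments$record_id))
  one_param <- function(p) {
    yt <- pairs[[paste0(p, "_true")]]
    yp <- pairs[[paste0(p, "_pred")]]
    m <- bp_metrics(yt, yp)
    ba <- bland_altman(yt, yp)
    dplyr::bind_cols(
      tibble::tibble(parameter = toupper(p)), m,
      dplyr::rename_with(bhs_grade(abs(yt - yp)), ~ paste0("bhs_", .x)),
      dplyr::rename_with(
        aami_check(ba$mean_diff, ba$sd_diff, n_records)[, c("pass"), drop = FALSE],
        ~ paste0("aami_", .x)),
      dplyr::rename_with(ba, ~ paste0("ba_", .x))
    )
  }
  parameters <- dplyr::bind_rows(lapply(c("sbp", "dbp", "mbp"), one_param))
  wf <- bp_metrics(unlist(segments$abp), unlist(segments$pred_abp))
  structure(list(pairs = pairs, parameters = parameters, waveform = wf,
                 n_segments = nrow(segments), n_records = n_records),
            class = "bp_evaluation")
}

#' @export
print.bp_evaluation <- function(x, ...) {
  cat("Blood-pressure evaluation over", x$n_segments, "segments from",
      x$n_records, "records\n")
  p <- x$parameters
  for (i in seq_len(nrow(p))) {
    cat(sprintf("  %s: MAE %5.2f  ME %+6.2f  SD %5.2f mmHg  BHS %s  AAMI %s\n",
                p$parameter[i], p$mae[i], p$me[i], p$ba_sd_diff[i],
                p$bhs_grade[i], ifelse(p$aami_pass[i], "pass", "fail")))
  }
  cat(sprintf("  waveform: MAE %.2f mmHg  RMSE %.2f  R2 %.3f\n",
              x$waveform$mae, x$waveform$std_eq20, x$waveform$r2))
  invisible(x)
}

#' Tidy per-parameter evaluation results
#'
#' @param x A `bp_evaluation`.
#' @param ... Unused.
#' @return The per-parameter metrics tibble (one row per SBP/DBP/MBP).
#' @export
tidy.bp_evaluation <- function(x, ...) x$parameters

#' One-row evaluation summary
#'
#' @param x A `bp_evaluation`.
#' @param ... Unused.
#' @return One-row tibble: pooled waveform metrics, worst BHS grade, overall
#'   AAMI verdict, segment/record counts.
#' @export
glance.bp_evaluation <- function(x, ...) {
  grades <- x$parameters$bhs_grade
  tibble::tibble(
    waveform_mae = x$waveform$mae,
    waveform_rmse = x$waveform$std_eq20,
    waveform_r2 = x$waveform$r2,
    worst_bhs_grade = c("A", "B", "C", "D")[max(match(grades, c("A", "B", "C", "D")))],
    aami_all_pass = all(x$parameters$aami_pass),
    n_segments = x$n_segments,
    n_records = x$n_records
  )
}

#' Serialize an evaluation report to JSON and CSV
#'
#' Writes `report.json` (full report; round-trips via [read_evaluation()])
#' and `metrics.csv` (per-parameter table) into a directory.
#'
#' @param x A `bp_evaluation`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_evaluation <- function(x, dir) {
  stopifnot(inherits(x, "bp_evaluation"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(
    list(parameters = x$parameters, waveform = x$waveform,
         pairs = x$pairs, n_segments = x$n_segments, n_records = x$n_records),
    file.path(dir, "report.json"), digits = NA, auto_unbox = TRUE
  )
  readr::write_csv(x$parameters, file.path(dir, "metrics.csv"))
  invisible(dir)
}

#' @rdname write_evaluation
#' @param path Path to a `report.json` written by [write_evaluation()].
#' @export
read_evaluation <- function(path) {
  if (dir.exists(path)) path <- file.path(path, "report.json")
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(pairs = tibble::as_tibble(j$pairs),
                 parameters = tibble::as_tibble(j$parameters),
                 waveform = tibble::as_tibble(j$waveform),
                 n_segments = j$n_segments, n_records = j$n_records),
            class = "bp_evaluation")
}
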