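#' Construct a single physiological record
#'
#' A record bundles synchronized PPG and ABP sample sequences acquired at a
#' common sampling rate. PPG is in arbitrary (sensor) units, ABP in mmHg.
#'
#' @param record_id Character scalar identifying the record.
#' @param ppg,abp Numeric vectors of equal length.
#' @param fs Sampling rate in Hz (default 125).
#' @return A one-row tibble with list-columns `ppg` and `abp`, plus
#'   `record_id`, `fs`, `n_samples` and `duration_s`.
#' @export
#' @examples
#' bp_record("r1", ppg = sin(1:250 / 10), abp = 100 + 20 * sin(1:250 / 10))
bp_record <- function(record_id, ppg, abp, fs = 125) {
  stopifnot(is.character(record_id), length(record_id) == 1L)
  ppg <- as.double(ppg)
  abp <- as.double(abp)
  if (length(ppg) != length(abp)) {
    stop("`ppg` and `abp` must have the same length (synchronized channels), got ",
         length(ppg), " and ", length(abp), call. = FALSE)
  }
  if (!is.numeric(fs) || length(fs) != 1L || fs <= 0) {
    stop("`fs` must be a positive sampling rate in Hz", call. = FALSE)
  }
  n <- length(ppg)
  tibble::tibble(
    record_id = record_id,
    ppg = list(ppg),
    abp = list(abp),
    fs = as.double(fs),
    n_samples = n,
    duration_s = n / fs
  )
}

#' Bind records into a record set
#'
#' @param records A list of one-row record tibbles (from [bp_record()]) or a
#'   tibble already in record-set shape.
#' @param source Character tag describing where the records came from.
#' @return A tibble of records with attribute `source`; record ids must be
#'   unique.
#' @export
bp_record_set <- function(records, source = "memory") {
  rs <- if (inherits(records, "data.frame")) tibble::as_tibble(records)
        else dplyr::bind_rows(records)
  required <- c("record_id", "ppg", "abp", "fs", "n_samples")
  missing <- setdiff(required, names(rs))
  if (length(missing)) {
    stop("record set is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (anyDuplicated(rs$record_id)) {
    stop("record ids must be unique within a record set", call. = FALSE)
  }
  if (!"duration_s" %in% names(rs)) rs$duration_s <- rs$n_samples / rs$fs
  attr(rs, "source") <- source
  rs
}

# internal: validate a segment tibble (windowed training samples)
check_segments <- function(segments, require_pred = FALSE) {
  required <- c("record_id", "offset", "ppg", "abp")
  if (require_pred) required <- c(required, "pred_abp")
  missing <- setdiff(required, names(segments))
  if (length(missing)) {
    stop("segment table is missing column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  len <- lengths(segments$ppg)
  if (length(len) && any(len != lengths(segments$abp))) {
    stop("ppg/abp segment lengths differ", call. = FALSE)
  }
  invisible(segments)
}

# internal: stack a list-column of equal-length vectors into an n x L matrix
segments_matrix <- function(col) {
  if (!length(col)) return(matrix(numeric(0), 0, 0))
  do.call(rbind, lapply(col, as.double))
}
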