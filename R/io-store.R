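#' Read a paired PPG/ABP record from CSV
#'
#' The CSV must contain columns `ppg` and `abp` (a leading time or index
#' column is permitted and ignored). One file holds one record.
#'
#' @param path Path to a CSV file.
#' @param fs Sampling rate in Hz (default 125).
#' @param record_id Identifier for the record; defaults to the file name.
#' @return A one-record record-set tibble.
#' @export
read_csv_records <- function(path, fs = 125, record_id = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  for (col in c("ppg", "abp")) {
    if (!col %in% names(df)) {
      stop("CSV '", path, "' is missing required column '", col, "'",
           call. = FALSE)
    }
  }
  bp_record_set(bp_record(record_id, ppg = df$ppg, abp = df$abp, fs = fs),
                source = path)
}

#' Write a segment table to an on-disk dataset store
#'
#' Persists windowed PPG/ABP segment pairs (with split membership and
#' normalization metadata) to a directory containing a Parquet table plus a
#' JSON metadata sidecar. Doubles round-trip bit-exactly.
#'
#' @param segments Segment tibble with columns `record_id`, `offset`, `ppg`,
#'   `abp` (list-columns), and optionally `split`, `norm_mu`, `norm_sigma`.
#' @param path Directory to create/overwrite.
#' @param fs Sampling rate recorded in the metadata.
#' @return `path`, invisibly.
#' @export
write_segment_store <- function(segments, path, fs = 125) {
  check_segments(segments)
  if (!"split" %in% names(segments)) segments$split <- "train"
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  arrow::write_parquet(
    segments[, intersect(c("split", "record_id", "offset", "ppg", "abp",
                           "norm_mu", "norm_sigma"), names(segments))],
    file.path(path, "segments.parquet")
  )
  meta <- list(
    fs = fs,
    window_len = if (nrow(segments)) length(segments$ppg[[1]]) else NA_integer_,
    n_segments = nrow(segments),
    splits = as.list(table(segments$split))
  )
  if (all(c("norm_mu", "norm_sigma") %in% names(segments)) && nrow(segments)) {
    meta$abp_norm <- list(mu = segments$norm_mu[[1]], sigma = segments$norm_sigma[[1]])
  }
  jsonlite::write_json(meta, file.path(path, "meta.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a segment store written by [write_segment_store()]
#'
#' @param path Store directory.
#' @param split Optional split name(s) to keep (`"train"`, `"val"`, `"test"`);
#'   default keeps everything. Requesting a split with no segments returns an
#'   empty table, not an error.
#' @return Segment tibble; store metadata is attached as attribute `meta`.
#' @export
read_segment_store <- function(path, split = NULL) {
  pq <- file.path(path, "segments.parquet")
  if (!file.exists(pq)) stop("no segment store at '", path, "'", call. = FALSE)
  seg <- tibble::as_tibble(arrow::read_parquet(pq))
  seg$ppg <- lapply(seg$ppg, as.double)
  seg$abp <- lapply(seg$abp, as.double)
  if (!is.null(split)) seg <- seg[seg$split %in% split, , drop = FALSE]
  meta <- jsonlite::read_json(file.path(path, "meta.json"), simplifyVector = TRUE)
  attr(seg, "meta") <- meta
  seg
}
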