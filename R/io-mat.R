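# Reader for MATLAB level-5 (.mat) containers holding one cell array of
# multi-channel records, the layout used by the UCI cuff-less BP distribution
# (Part_1..Part_4, 3000 cells each; one row per signal channel at 125 Hz).
#
# Only the v5 binary dialect is supported. v7.3 files are HDF5 containers and
# are detected and rejected with an informative error. Supported element
# types: numeric arrays (int8..uint32, single, double), cell arrays, and
# zlib-compressed elements.

MI_INT8 <- 1L; MI_UINT8 <- 2L; MI_INT16 <- 3L; MI_UINT16 <- 4L
MI_INT32 <- 5L; MI_UINT32 <- 6L; MI_SINGLE <- 7L; MI_DOUBLE <- 9L
MI_COMPRESSED <- 15L; MI_MATRIX <- 14L
MX_CELL <- 1L

mat5_read_numeric <- function(raw, type, nbytes) {
  n <- switch(as.character(type),
    "1" = nbytes, "2" = nbytes, "3" = nbytes %/% 2L, "4" = nbytes %/% 2L,
    "5" = nbytes %/% 4L, "6" = nbytes %/% 4L, "7" = nbytes %/% 4L,
    "9" = nbytes %/% 8L,
    stop("unsupported MAT data type ", type, call. = FALSE))
  switch(as.character(type),
    "1" = as.double(readBin(raw, "integer", n, size = 1L, signed = TRUE,  endian = "little")),
    "2" = as.double(readBin(raw, "integer", n, size = 1L, signed = FALSE, endian = "little")),
    "3" = as.double(readBin(raw, "integer", n, size = 2L, signed = TRUE,  endian = "little")),
    "4" = as.double(readBin(raw, "integer", n, size = 2L, signed = FALSE, endian = "little")),
    "5" = as.double(readBin(raw, "integer", n, size = 4L, endian = "little")),
    "6" = as.double(readBin(raw, "integer", n, size = 4L, endian = "little")),
    "7" = readBin(raw, "double", n, size = 4L, endian = "little"),
    "9" = readBin(raw, "double", n, size = 8L, endian = "little"))
}

# Parse one data element starting at `pos` (1-based). Returns
# list(type, value, end) where `end` is the first position after the element
# (8-byte aligned).
mat5_parse_element <- function(r, pos, want_value = TRUE) {
  tagword <- readBin(r[pos:(pos + 3L)], "integer", 1L, size = 4L, endian = "little")
  small_size <- bitwAnd(bitwShiftR(tagword, 16L), 0xFFFFL)
  if (small_size != 0L) {            # small data element: data packed in tag
    type <- bitwAnd(tagword, 0xFFFFL)
    nbytes <- small_size
    data <- r[(pos + 4L):(pos + 3L + nbytes)]
    end <- pos + 8L
  } else {
    type <- tagword
    nbytes <- readBin(r[(pos + 4L):(pos + 7L)], "integer", 1L, size = 4L, endian = "little")
    data <- if (nbytes > 0L) r[(pos + 8L):(pos + 7L + nbytes)] else raw(0)
    end <- pos + 8L + nbytes
    if (type != MI_COMPRESSED) end <- pos + 8L + 8L * ((nbytes + 7L) %/% 8L)
  }
  value <- NULL
  if (want_value) {
    if (type == MI_COMPRESSED) {
      inner <- memDecompress(data, type = "gzip")
      value <- mat5_parse_element(inner, 1L)$value
      type <- MI_MATRIX
    } else if (type == MI_MATRIX) {
      value <- mat5_parse_matrix(data)
    } else {
      value <- mat5_read_numeric(data, type, nbytes)
    }
  }
  list(type = type, value = value, end = end)
}

# Parse the subelements of an miMATRIX payload into either a numeric matrix
# (with dim set) or a list of parsed cells.
mat5_parse_matrix <- function(r) {
  flags <- mat5_parse_element(r, 1L)
  class_id <- bitwAnd(as.integer(flags$value[1L]), 0xFFL)
  dims_el <- mat5_parse_element(r, flags$end)
  dims <- as.integer(dims_el$value)
  name_el <- mat5_parse_element(r, dims_el$end, want_value = FALSE)
  pos <- name_el$end
  if (class_id == MX_CELL) {
    n_cells <- prod(dims)
    cells <- vector("list", n_cells)
    for (i in seq_len(n_cells)) {
      el <- mat5_parse_element(r, pos)
      cells[[i]] <- el$value
      pos <- el$end
    }
    return(cells)
  }
  # numeric array: next subelement is the real part
  pr <- mat5_parse_element(r, pos)
  x <- pr$value
  if (length(dims) == 2L) dim(x) <- dims else dim(x) <- dims
  x
}

#' Read a MATLAB cell-array container of PPG/ABP records
#'
#' Reads a MATLAB level-5 `.mat` file holding one cell array in which each
#' cell is a numeric matrix with one row per signal channel (conventionally
#' PPG, ABP, ECG) sampled at a common rate. This is the layout of the UCI
#' cuff-less blood pressure container files (`Part_1.mat` .. `Part_4.mat`,
#' 3000 cells each, 125 Hz).
#'
#' Cells with fewer than two rows cannot supply both channels; they are
#' skipped with a warning and counted in the `skipped` attribute of the
#' result. MATLAB v7.3 files (HDF5-based) are not supported and raise an
#' error identifying the dialect.
#'
#' @param path Path to the `.mat` file.
#' @param channel_map Named integer vector giving the 1-based row index of
#'   each channel; default `c(ppg = 1, abp = 2)` (any ECG row is ignored).
#' @param fs Sampling rate in Hz attached to every record (default 125).
#' @return A record-set tibble (see [bp_record_set()]); one record per cell,
#'   `record_id = "<filename>#<cell index>"`.
#' @export
read_matlab_records <- function(path, channel_map = c(ppg = 1L, abp = 2L), fs = 125) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  r <- readBin(path, "raw", file.size(path))
  if (length(r) >= 8L && identical(r[1:8], charToRaw("\x89HDF\r\n\x1a\n"))) {
    stop("'", path, "' is a MATLAB v7.3 (HDF5-based) file; only the v5 dialect ",
         "is supported. Re-save with '-v5' or convert to CSV.", call. = FALSE)
  }
  if (length(r) < 136L) stop("'", path, "' is too short to be a MAT v5 file", call. = FALSE)
  endian <- rawToChar(r[127:128])
  if (endian != "IM") {
    stop("'", path, "' is not a little-endian MAT v5 file (endian indicator '",
         endian, "')", call. = FALSE)
  }
  stopifnot(all(c("ppg", "abp") %in% names(channel_map)))

  # scan top-level elements for the first cell array
  pos <- 129L
  cells <- NULL
  while (pos + 7L <= length(r)) {
    el <- mat5_parse_element(r, pos)
    if (is.list(el$value)) { cells <- el$value; break }
    pos <- el$end
  }
  if (is.null(cells)) {
    stop("'", path, "' contains no cell array; expected one cell array of ",
         "channel-by-sample record matrices", call. = FALSE)
  }

  fname <- basename(path)
  skipped <- 0L
  records <- vector("list", length(cells))
  for (i in seq_along(cells)) {
    m <- cells[[i]]
    if (!is.matrix(m) || nrow(m) < max(channel_map[c("ppg", "abp")])) {
      skipped <- skipped + 1L
      next
    }
    records[[i]] <- bp_record(
      record_id = paste0(fname, "#", i),
      ppg = m[channel_map[["ppg"]], ],
      abp = m[channel_map[["abp"]], ],
      fs = fs
    )
  }
  if (skipped > 0L) {
    warning(skipped, " cell(s) in '", fname,
            "' had fewer rows than the channel map requires and were skipped",
            call. = FALSE)
  }
  records <- records[!vapply(records, is.null, logical(1))]
  out <- if (length(records)) bp_record_set(records, source = path)
         else bp_record_set(empty_record_set(), source = path)
  attr(out, "skipped") <- skipped
  out
}

# internal: a zero-row record-set tibble with the right columns
empty_record_set <- function() {
  tibble::tibble(
    record_id = character(0), ppg = list(), abp = list(),
    fs = double(0), n_samples = integer(0), duration_s = double(0)
  )
}
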