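# File I/O: plain-text persistence for recordings/features and a minimal
# MAT v5 reader for NinaPro subject files.
#
# Note on intermediates: no HDF5 binding ships with the supported R stack,
# so recordings are persisted as TSV with a JSON metadata header line.
# The layout mirrors the HDF5 datasets a Python pipeline would use
# (emg samples x channels, stimulus, repetition; attributes fs, subject).

#' Save a recording as tab-separated text
#'
#' First line is a `#` comment carrying JSON metadata (`fs`, `subject`);
#' then a header row and one row per sample: channels, stimulus,
#' repetition.  Read back with [load_recording()]; the round trip is exact
#' to full double precision.
#'
#' @param recording an [emg_recording()].
#' @param path output file path (written atomically via a temp file).
#' @return `path`, invisibly.
#' @export
save_recording <- function(recording, path) {
  stopifnot(inherits(recording, "emg_recording"))
  nc <- ncol(recording$emg)
  df <- as.data.frame(recording$emg)
  names(df) <- paste0("ch", seq_len(nc))
  df$stimulus <- recording$stimulus
  df$repetition <- recording$repetition
  tmp <- paste0(path, ".tmp")
  con <- file(tmp, "w")
  writeLines(paste0("# ", jsonlite::toJSON(
    list(fs = recording$fs, subject = recording$subject),
    auto_unbox = TRUE)), con)
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = TRUE),
                     con, sep = "\t", quote = FALSE, row.names = FALSE)
  close(con)
  file.rename(tmp, path)
  invisible(path)
}

#' Load a recording saved by [save_recording()]
#' @param path file path.
#' @return an [emg_recording()].
#' @export
load_recording <- function(path) {
  first <- readLines(path, n = 1L)
  if (!startsWith(first, "# "))
    stop("load_recording: missing metadata header in ", path)
  meta <- jsonlite::fromJSON(sub("^# ", "", first))
  df <- utils::read.table(path, header = TRUE, sep = "\t", comment.char = "#")
  chcols <- grep("^ch[0-9]+$", names(df))
  emg_recording(as.matrix(df[, chcols, drop = FALSE]), df$stimulus,
                df$repetition, fs = meta$fs, subject = meta$subject)
}

## ---- minimal MAT v5 reader -------------------------------------------

mat5_read_element <- function(raw, pos) {
  tag <- readBin(raw[pos:(pos + 3L)], "integer", 1L, 4L, endian = "little")
  small <- bitwAnd(bitwShiftR(tag, 16L), 0xFFFFL)
  if (small != 0L) {                       # small-element format
    type <- bitwAnd(tag, 0xFFFFL)
    size <- small
    data <- raw[(pos + 4L):(pos + 3L + size)]
    return(list(type = type, data = data, next_pos = pos + 8L))
  }
  type <- tag
  size <- readBin(raw[(pos + 4L):(pos + 7L)], "integer", 1L, 4L,
                  endian = "little")
  data <- if (size > 0L) raw[(pos + 8L):(pos + 7L + size)] else raw(0)
  adv <- 8L + size
  if (type != 15L) adv <- adv + (-size %% 8L)   # pad to 8-byte boundary
  list(type = type, data = data, next_pos = pos + adv)
}

mat5_numeric <- function(type, data) {
  switch(as.character(type),
    "1" = as.integer(readBin(data, "integer", length(data), 1L, TRUE,
                             endian = "little")),
    "2" = as.integer(readBin(data, "integer", length(data), 1L, FALSE,
                             endian = "little")),
    "3" = readBin(data, "integer", length(data) / 2L, 2L, TRUE,
                  endian = "little"),
    "4" = readBin(data, "integer", length(data) / 2L, 2L, FALSE,
                  endian = "little"),
    "5" = readBin(data, "integer", length(data) / 4L, 4L, TRUE,
                  endian = "little"),
    "6" = {  # uint32: reinterpret the signed read, promote to double
      v <- readBin(data, "integer", length(data) / 4L, 4L, endian = "little")
      v + (v < 0) * 2^32
    },
    "7" = readBin(data, "numeric", length(data) / 4L, 4L,
                  endian = "little"),
    "9" = readBin(data, "numeric", length(data) / 8L, 8L,
                  endian = "little"),
    stop("load_ninapro_mat: unsupported numeric storage type ", type))
}

mat5_parse_matrix <- function(data) {
  pos <- 1L
  flags <- mat5_read_element(data, pos); pos <- flags$next_pos
  dims_el <- mat5_read_element(data, pos); pos <- dims_el$next_pos
  dims <- readBin(dims_el$data, "integer", length(dims_el$data) / 4L, 4L,
                  endian = "little")
  name_el <- mat5_read_element(data, pos); pos <- name_el$next_pos
  name <- rawToChar(name_el$data[name_el$data != as.raw(0)])
  real_el <- mat5_read_element(data, pos)
  values <- mat5_numeric(real_el$type, real_el$data)
  if (length(values) != prod(dims))
    stop("load_ninapro_mat: variable '", name, "' has ", length(values),
         " values for declared dims ", paste(dims, collapse = "x"))
  list(name = name, value = array(as.numeric(values), dim = dims))
}

#' Read numeric variables from a MATLAB v5 (Level 5) MAT file
#'
#' Supports real full numeric matrices stored uncompressed or
#' zlib-compressed (the layout written by MATLAB and `scipy.io.savemat`),
#' which covers the NinaPro subject files.  Cell arrays, structs, sparse
#' and complex data are skipped.
#'
#' @param path MAT file path.
#' @return named list of numeric arrays.
#' @export
read_mat5 <- function(path) {
  raw <- readBin(path, "raw", file.size(path))
  if (length(raw) < 128L) stop("read_mat5: ", path, " is not a MAT v5 file")
  endian <- rawToChar(raw[127:128])
  if (endian != "IM")
    stop("read_mat5: only little-endian MAT v5 files are supported")
  vars <- list()
  pos <- 129L
  while (pos + 7L <= length(raw)) {
    el <- mat5_read_element(raw, pos)
    payload <- el$data
    type <- el$type
    if (type == 15L) {                     # zlib-compressed element
      payload <- memDecompress(payload, type = "gzip")
      inner <- mat5_read_element(payload, 1L)
      type <- inner$type
      payload <- inner$data
    }
    if (type == 14L) {                     # miMATRIX
      m <- tryCatch(mat5_parse_matrix(payload), error = function(e) NULL)
      if (!is.null(m)) vars[[m$name]] <- m$value
    }
    pos <- el$next_pos
  }
  vars
}

#' Load a NinaPro subject MAT file as an [emg_recording()]
#'
#' Expects variables `emg` (samples x channels), `stimulus` (or the refined
#' `restimulus` when `use_restimulus = TRUE`) and `repetition` (or
#' `rerepetition`).  DB1 files carry 10 channels at 100 Hz; `db2 = TRUE`
#' switches the expectation to 12 channels at 2000 Hz.
#'
#' @param path MAT file path.
#' @param db2 logical; DB2-mode channel count and sampling rate.
#' @param use_restimulus use the relabelled stimulus stream if present.
#' @param subject subject id to attach (default: `subject` variable in the
#'   file if present, else `NA`).
#' @return an [emg_recording()].
#' @export
load_ninapro_mat <- function(path, db2 = FALSE, use_restimulus = FALSE,
                             subject = NULL) {
  vars <- read_mat5(path)
  if (is.null(vars$emg))
    stop("load_ninapro_mat: missing variable 'emg' in ", path)
  stim_name <- if (use_restimulus && !is.null(vars$restimulus))
    "restimulus" else "stimulus"
  if (is.null(vars[[stim_name]]))
    stop("load_ninapro_mat: missing variable '", stim_name, "' in ", path)
  rep_name <- if (use_restimulus && !is.null(vars$rerepetition))
    "rerepetition" else "repetition"
  if (is.null(vars[[rep_name]]))
    stop("load_ninapro_mat: missing variable '", rep_name, "' in ", path)
  expected_ch <- if (db2) 12L else 10L
  fs <- if (db2) 2000 else 100
  emg <- vars$emg
  if (length(dim(emg)) != 2L || ncol(emg) != expected_ch)
    stop("load_ninapro_mat: expected ", expected_ch, " channels, found ",
         if (length(dim(emg)) == 2L) ncol(emg) else "non-matrix emg")
  if (is.null(subject))
    subject <- if (!is.null(vars$subject)) as.integer(vars$subject[1])
               else NA_integer_
  emg_recording(emg, as.vector(vars[[stim_name]]),
                as.vector(vars[[rep_name]]), fs = fs, subject = subject)
}
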