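#' Continuous EEG recording container
#'
#' A lightweight container for continuous multichannel EEG: a channels x
#' samples matrix of microvolt values, the sampling rate, ordered channel
#' labels and an (arbitrary-origin) acquisition start time.
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param fs sampling rate in Hz.
#' @param channels character vector of unique channel labels, one per row.
#' @param t0 acquisition start time in seconds (arbitrary origin).
#' @return An object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, fs, channels, t0 = 0) {
  data <- as.matrix(data)
  if (fs <= 0) abort("`fs` must be positive.")
  if (anyDuplicated(channels)) abort("channel labels must be unique.")
  if (nrow(data) != length(channels))
    abort("`data` must have one row per channel label.")
  rownames(data) <- channels
  structure(list(data = data, fs = fs, channels = as.character(channels),
                 t0 = t0),
            class = "eeg_recording")
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf("<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n",
              nrow(x$data), ncol(x$data), x$fs, ncol(x$data) / x$fs))
  cat("  channels:", paste(x$channels, collapse = ", "), "\n")
  invisible(x)
}

## ---- minimal plain-EDF codec (16-bit, physical units microvolts) ----------

edf_pad <- function(s, width) {
  s <- substr(s, 1, width)
  formatC(s, width = width, flag = "-")
}

#' Write a recording to a plain EDF file
#'
#' Writes 16-bit EDF with one-second data records and per-channel symmetric
#' physical ranges in microvolts.  The recording is truncated to a whole
#' number of seconds (EDF stores an integer number of fixed-duration
#' records); a warning reports any truncation.
#'
#' @param rec an [eeg_recording()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_eeg_edf <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  fs <- rec$fs
  if (abs(fs - round(fs)) > 1e-9)
    abort("EDF writer requires an integer sampling rate.")
  fs <- as.integer(round(fs))
  n_rec <- ncol(rec$data) %/% fs
  if (n_rec < 1) abort("recording shorter than one EDF data record (1 s).")
  if (n_rec * fs < ncol(rec$data))
    warn(sprintf("EDF writer: truncating %d trailing samples (partial second).",
                 ncol(rec$data) - n_rec * fs))
  x <- rec$data[, seq_len(n_rec * fs), drop = FALSE]
  ns <- nrow(x)

  pmax_ch <- pmax(1, ceiling(apply(abs(x), 1, max) * 1.05))
  dmin <- -32768L; dmax <- 32767L

  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  wr <- function(s, width) writeChar(edf_pad(s, width), con, nchars = width,
                                     eos = NULL)
  wr("0", 8)
  wr("X", 80)                                   # patient id
  wr("Startdate X", 80)                         # recording id
  wr("01.01.00", 8); wr("00.00.00", 8)          # date, time (arbitrary origin)
  wr(format(256L + ns * 256L), 8)               # header bytes
  wr("", 44)
  wr(format(n_rec), 8)
  wr("1", 8)                                    # record duration, seconds
  wr(format(ns), 4)
  for (lab in rec$channels) wr(lab, 16)
  for (i in seq_len(ns)) wr("", 80)             # transducer
  for (i in seq_len(ns)) wr("uV", 8)
  for (i in seq_len(ns)) wr(format(-pmax_ch[i]), 8)
  for (i in seq_len(ns)) wr(format(pmax_ch[i]), 8)
  for (i in seq_len(ns)) wr(format(dmin), 8)
  for (i in seq_len(ns)) wr(format(dmax), 8)
  for (i in seq_len(ns)) wr("", 80)             # prefiltering
  for (i in seq_len(ns)) wr(format(fs), 8)
  for (i in seq_len(ns)) wr("", 32)

  scale <- (dmax - dmin) / (2 * pmax_ch)
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1) * fs + 1):(r * fs)
    for (i in seq_len(ns)) {
      dig <- round((x[i, cols] + pmax_ch[i]) * scale[i]) + dmin
      dig <- pmin(pmax(dig, dmin), dmax)
      writeBin(as.integer(dig), con, size = 2, endian = "little")
    }
  }
  invisible(path)
}

read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  rd <- function(width) trimws(readChar(con, width, useBytes = TRUE))
  num <- function(width, what) {
    v <- suppressWarnings(as.numeric(rd(width)))
    if (is.na(v)) abort(sprintf("malformed EDF header: field '%s'.", what))
    v
  }
  if (rd(8) != "0") abort("malformed EDF header: unsupported version field.")
  rd(80); rd(80); rd(8); rd(8)
  num(8, "header bytes"); rd(44)
  n_rec <- num(8, "number of data records")
  dur <- num(8, "record duration")
  ns <- as.integer(num(4, "number of signals"))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)
  for (i in seq_len(ns)) rd(8)
  pmin_ch <- vapply(seq_len(ns), function(i) num(8, "physical minimum"), 0)
  pmax_ch <- vapply(seq_len(ns), function(i) num(8, "physical maximum"), 0)
  dmin_ch <- vapply(seq_len(ns), function(i) num(8, "digital minimum"), 0)
  dmax_ch <- vapply(seq_len(ns), function(i) num(8, "digital maximum"), 0)
  for (i in seq_len(ns)) rd(80)
  spr <- vapply(seq_len(ns), function(i) num(8, "samples per record"), 0)
  for (i in seq_len(ns)) rd(32)

  fs <- spr / dur
  if (length(unique(fs)) != 1)
    abort("EDF reader supports one common sampling rate across signals.")
  out <- matrix(0, ns, n_rec * spr[1])
  gain <- (pmax_ch - pmin_ch) / (dmax_ch - dmin_ch)
  for (r in seq_len(n_rec)) {
    for (i in seq_len(ns)) {
      dig <- readBin(con, integer(), n = spr[i], size = 2, endian = "little",
                     signed = TRUE)
      if (length(dig) < spr[i]) abort("EDF file truncated mid-record.")
      out[i, ((r - 1) * spr[i] + 1):(r * spr[i])] <-
        (dig - dmin_ch[i]) * gain[i] + pmin_ch[i]
    }
  }
  eeg_recording(out, fs[1], labels)
}

## ---- delimited-text dialect ------------------------------------------------

read_eeg_tsv <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (ncol(raw) < 2 || names(raw)[1] != "time")
    abort("EEG TSV must have a 'time' column followed by channel columns.")
  for (j in seq_along(raw)) {
    v <- suppressWarnings(as.numeric(raw[[j]]))
    bad <- which(is.na(v))
    if (length(bad))
      abort(sprintf("EEG TSV: non-numeric value in column '%s', row %d.",
                    names(raw)[j], bad[1]))
    raw[[j]] <- v
  }
  tt <- raw$time
  if (length(tt) < 2) abort("EEG TSV needs at least two samples.")
  fs <- 1 / stats::median(diff(tt))
  eeg_recording(t(as.matrix(raw[-1])), round(fs, 6), names(raw)[-1],
                t0 = tt[1])
}

#' Write a recording to the TSV dialect
#'
#' Plain tab-separated text with a `time` column (seconds) followed by one
#' microvolt column per channel; round-trips through [read_continuous_eeg()].
#'
#' @inheritParams write_eeg_edf
#' @return `path`, invisibly.
#' @export
write_eeg_tsv <- function(rec, path) {
  stopifnot(inherits(rec, "eeg_recording"))
  df <- tibble(time = rec$t0 + (seq_len(ncol(rec$data)) - 1) / rec$fs)
  for (ch in rec$channels) df[[ch]] <- rec$data[ch, ]
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}

#' Read continuous EEG from EDF or TSV
#'
#' @param path file path.
#' @param dialect `"edf"`, `"tsv"`, or `"auto"` (by file extension).
#' @return An [eeg_recording()] in microvolts, channel order as in the file.
#' @export
read_continuous_eeg <- function(path, dialect = c("auto", "edf", "tsv")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- switch(ext, edf = "edf", tsv = "tsv", txt = "tsv",
                      abort(sprintf("unknown dialect for extension '.%s'.", ext)))
  }
  switch(dialect, edf = read_edf(path), tsv = read_eeg_tsv(path))
}

## ---- events and gaze -------------------------------------------------------

#' Read a trial event table
#'
#' Expects tab-separated columns `trial_id`, `condition`, and either
#' `onset_sample` or `onset_time_s` (converted to samples by rounding
#' `t * fs` to the nearest sample, ties half up).
#'
#' @param path file path.
#' @param fs sampling rate in Hz; required when only `onset_time_s` is given.
#' @return A tibble with columns `trial_id`, `onset_sample`, `condition`,
#'   sorted by onset.
#' @export
read_events <- function(path, fs = NULL) {
  ev <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  if (!all(c("trial_id", "condition") %in% names(ev)))
    abort("event table must have 'trial_id' and 'condition' columns.")
  if (!"onset_sample" %in% names(ev)) {
    if (!"onset_time_s" %in% names(ev))
      abort("event table must have 'onset_sample' or 'onset_time_s'.")
    if (is.null(fs))
      abort("`fs` is required to convert 'onset_time_s' to samples.")
    ev$onset_sample <- as.integer(floor(ev$onset_time_s * fs + 0.5))
  }
  validate_events(ev[c("trial_id", "onset_sample", "condition")])
}

validate_events <- function(ev) {
  if (anyDuplicated(ev$trial_id))
    abort(sprintf("duplicate trial_id: %s",
                  ev$trial_id[anyDuplicated(ev$trial_id)][1]))
  bad <- setdiff(unique(ev$condition), CONDITION_VOCAB)
  if (length(bad))
    abort(sprintf("condition '%s' outside vocabulary {%s}.", bad[1],
                  paste(CONDITION_VOCAB, collapse = ", ")))
  ev <- dplyr::arrange(as_tibble(ev), .data$onset_sample)
  if (any(diff(ev$onset_sample) <= 0))
    abort("event onsets must be strictly increasing.")
  ev
}

#' Read a gaze-sample table
#'
#' Expects tab-separated columns `time_s`, `x`, `y`, `valid`.  Invalid rows
#' are retained with `valid = FALSE` (the gap-interpolation logic needs
#' them).
#'
#' @param path file path.
#' @return A tibble with columns `time_s`, `x`, `y`, `valid` (logical).
#' @export
read_gaze <- function(path) {
  gs <- readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
  need <- c("time_s", "x", "y", "valid")
  miss <- setdiff(need, names(gs))
  if (length(miss))
    abort(sprintf("gaze table missing column(s): %s.",
                  paste(miss, collapse = ", ")))
  if (any(diff(gs$time_s) < 0))
    abort("gaze times must be non-decreasing.")
  gs$valid <- as.logical(gs$valid)
  as_tibble(gs[need])
}

#' Write a feature or reliability table
#'
#' Header plus one line per record, doubles at full (round-trippable)
#' precision.
#'
#' @param rows a data frame of homogeneous records.
#' @param path output path.
#' @param dialect `"csv"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
write_table <- function(rows, path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") readr::write_csv(rows, path, progress = FALSE)
  else readr::write_tsv(rows, path, progress = FALSE)
  invisible(path)
}

#' Read back a table written by [write_table()]
#'
#' @inheritParams write_table
#' @return A tibble.
#' @export
read_table_rows <- function(path, dialect = c("csv", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "csv") readr::read_csv(path, col_types = readr::cols(),
                                        progress = FALSE)
  else readr::read_tsv(path, col_types = readr::cols(), progress = FALSE)
}
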