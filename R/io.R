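# File interchange: EDF for EEG, WAV for stimulus audio, CSV for tabular
# data. The EDF and WAV codecs are deliberately minimal (continuous
# recordings, 16-bit integer EDF samples; PCM16 / float32 WAV) — enough for
# faithful round-trips of the pipeline's own objects.

pad_field <- function(x, width) {
  x <- substr(as.character(x), 1, width)
  formatC(x, width = width, flag = "-")
}

#' Write an EEG recording to an EDF file
#'
#' European Data Format, one 1-second data record per second of signal,
#' 16-bit samples scaled to each channel's physical range. The sampling
#' rate must be a whole number; a trailing partial second is dropped.
#'
#' @param recording an [eeg_recording].
#' @param path output file path.
#' @param seed optional generating seed; when given, a sidecar
#'   `<path>.json` records it alongside basic provenance.
#' @return `path`, invisibly.
#' @export
write_edf <- function(recording, path, seed = NULL) {
  data <- recording$data
  rate <- recording$rate
  if (abs(rate - round(rate)) > 1e-9)
    stop("EDF export requires an integer sampling rate")
  rate <- as.integer(round(rate))
  ns <- nrow(data)
  n_rec <- ncol(data) %/% rate
  if (n_rec < 1) stop("recording shorter than one EDF data record (1 s)")
  data <- data[, seq_len(n_rec * rate), drop = FALSE]
  pmin_ <- apply(data, 1L, min); pmax_ <- apply(data, 1L, max)
  flat <- pmax_ - pmin_ < 1e-12
  pmin_[flat] <- pmin_[flat] - 1; pmax_[flat] <- pmax_[flat] + 1
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- paste0(
    pad_field("0", 8), pad_field("synthetic", 80), pad_field("ctenvr", 80),
    pad_field("01.01.00", 8), pad_field("00.00.00", 8),
    pad_field(256 * (ns + 1), 8), pad_field("", 44),
    pad_field(n_rec, 8), pad_field("1", 8), pad_field(ns, 4))
  writeChar(hdr, con, eos = NULL)
  fields <- list(
    lab = vapply(recording$channel_labels, pad_field, "", width = 16),
    trans = rep(pad_field("", 80), ns),
    dim = rep(pad_field("uV", 8), ns),
    pmin = vapply(sprintf("%.8g", pmin_), pad_field, "", width = 8),
    pmax = vapply(sprintf("%.8g", pmax_), pad_field, "", width = 8),
    dmin = rep(pad_field("-32768", 8), ns),
    dmax = rep(pad_field("32767", 8), ns),
    pre = rep(pad_field("", 80), ns),
    spr = rep(pad_field(rate, 8), ns),
    res = rep(pad_field("", 32), ns))
  for (f in fields) writeChar(paste(f, collapse = ""), con, eos = NULL)
  gain <- (pmax_ - pmin_) / 65535
  for (r in seq_len(n_rec)) {
    cols <- ((r - 1L) * rate + 1L):(r * rate)
    for (chn in seq_len(ns)) {
      dig <- round((data[chn, cols] - pmin_[chn]) / gain[chn]) - 32768
      writeBin(as.integer(pmin(pmax(dig, -32768), 32767)), con, size = 2,
               endian = "little")
    }
  }
  if (!is.null(seed)) write_sidecar(path, seed)
  invisible(path)
}

#' Read an EDF file into an EEG recording
#'
#' Reads continuous EDF with equal per-channel sampling rates, honoring the
#' stored physical scaling (values returned in the stored physical unit,
#' microvolts for files written by [write_edf()]).
#'
#' @param path EDF file path.
#' @return an [eeg_recording].
#' @export
read_edf <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  rd <- function(w) trimws(readChar(con, w, useBytes = TRUE))
  rd(8); rd(80); rd(80); rd(8); rd(8)
  hdr_bytes <- as.integer(rd(8)); rd(44)
  n_rec <- as.integer(rd(8)); rec_dur <- as.numeric(rd(8))
  ns <- as.integer(rd(4))
  if (!isTRUE(ns > 0) || !isTRUE(n_rec > 0))
    stop(sprintf("malformed EDF header in %s", path))
  labels <- vapply(seq_len(ns), function(i) rd(16), "")
  for (i in seq_len(ns)) rd(80)      # transducer
  for (i in seq_len(ns)) rd(8)       # dimension
  pmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  pmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmin_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  dmax_ <- as.numeric(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(80)      # prefilter
  spr <- as.integer(vapply(seq_len(ns), function(i) rd(8), ""))
  for (i in seq_len(ns)) rd(32)      # reserved
  if (length(unique(spr)) != 1L)
    stop("EDF files with mixed per-channel rates are not supported")
  seek(con, hdr_bytes)
  data <- matrix(0, ns, n_rec * spr[1])
  gain <- (pmax_ - pmin_) / (dmax_ - dmin_)
  for (r in seq_len(n_rec)) {
    for (chn in seq_len(ns)) {
      dig <- readBin(con, "integer", spr[chn], size = 2, endian = "little")
      cols <- ((r - 1L) * spr[chn] + 1L):(r * spr[chn])
      data[chn, cols] <- (dig - dmin_[chn]) * gain[chn] + pmin_[chn]
    }
  }
  eeg_recording(data, spr[1] / rec_dur, labels)
}

#' Write a waveform to a mono 16-bit PCM WAV file
#'
#' @param audio numeric vector in `[-1, 1]` (clipped otherwise).
#' @param rate sampling rate in Hz.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_wav <- function(audio, rate, path) {
  x <- pmin(pmax(as.numeric(audio), -1), 1)
  pcm <- as.integer(round(x * 32767))
  n <- length(pcm)
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar("RIFF", con, eos = NULL)
  writeBin(as.integer(36 + 2 * n), con, size = 4, endian = "little")
  writeChar("WAVEfmt ", con, eos = NULL)
  writeBin(as.integer(16), con, size = 4, endian = "little")
  writeBin(as.integer(1), con, size = 2, endian = "little")   # PCM
  writeBin(as.integer(1), con, size = 2, endian = "little")   # mono
  writeBin(as.integer(rate), con, size = 4, endian = "little")
  writeBin(as.integer(rate * 2), con, size = 4, endian = "little")
  writeBin(as.integer(2), con, size = 2, endian = "little")
  writeBin(as.integer(16), con, size = 2, endian = "little")
  writeChar("data", con, eos = NULL)
  writeBin(as.integer(2 * n), con, size = 4, endian = "little")
  writeBin(pcm, con, size = 2, endian = "little")
  invisible(path)
}

#' Read a WAV file (PCM16 or float32, any standard rate)
#'
#' @param path WAV file path.
#' @return list with `audio` (numeric in `[-1, 1]`; channels averaged if
#'   multichannel) and `rate` (Hz).
#' @export
read_wav <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  if (readChar(con, 4, useBytes = TRUE) != "RIFF")
    stop(sprintf("%s: not a RIFF/WAV file", path))
  readBin(con, "integer", 1, 4, endian = "little")
  if (readChar(con, 4, useBytes = TRUE) != "WAVE")
    stop(sprintf("%s: not a WAV file", path))
  fmt <- NULL
  repeat {
    id <- readChar(con, 4, useBytes = TRUE)
    if (!nzchar(id)) stop(sprintf("%s: no data chunk found", path))
    size <- readBin(con, "integer", 1, 4, endian = "little")
    if (id == "fmt ") {
      fmt <- list(
        code = readBin(con, "integer", 1, 2, endian = "little"),
        channels = readBin(con, "integer", 1, 2, endian = "little"),
        rate = readBin(con, "integer", 1, 4, endian = "little"))
      readBin(con, "integer", 1, 4, endian = "little")
      readBin(con, "integer", 1, 2, endian = "little")
      fmt$bits <- readBin(con, "integer", 1, 2, endian = "little")
      if (size > 16) readBin(con, "raw", size - 16)
    } else if (id == "data") {
      if (is.null(fmt)) stop(sprintf("%s: data chunk before fmt", path))
      if (fmt$code == 1 && fmt$bits == 16) {
        x <- readBin(con, "integer", size / 2, 2, endian = "little") / 32768
      } else if (fmt$code == 3 && fmt$bits == 32) {
        x <- readBin(con, "numeric", size / 4, 4, endian = "little")
      } else {
        stop(sprintf("%s: unsupported WAV encoding (format %d, %d bit)",
                     path, fmt$code, fmt$bits))
      }
      if (fmt$channels > 1)
        x <- colMeans(matrix(x, nrow = fmt$channels))
      return(list(audio = x, rate = fmt$rate))
    } else {
      readBin(con, "raw", size + size %% 2)
    }
  }
}

write_sidecar <- function(path, seed, extra = list()) {
  jsonlite::write_json(
    c(list(file = basename(path), seed = seed,
           package = "ctenvr",
           created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S")), extra),
    paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' Write an envelope, cohort table, or trial records to CSV
#'
#' Plain CSV with documented headers; when `seed` is given a sidecar JSON
#' next to the file records the generating seed.
#'
#' @param x a [speech_envelope] or data.frame.
#' @param path output path.
#' @param seed optional generating seed for the sidecar.
#' @return `path`, invisibly.
#' @export
write_table_csv <- function(x, path, seed = NULL) {
  if (inherits(x, "speech_envelope")) {
    x <- data.frame(time = (seq_along(x$samples) - 1) / x$rate,
                    amplitude = x$samples)
  }
  utils::write.csv(x, path, row.names = FALSE)
  if (!is.null(seed)) write_sidecar(path, seed)
  invisible(path)
}

check_schema <- function(d, schema, path) {
  missing <- setdiff(names(schema), names(d))
  if (length(missing))
    stop(sprintf("%s: missing column(s): %s", path,
                 paste(missing, collapse = ", ")))
  for (col in names(schema)) {
    bad <- which(!schema[[col]](d[[col]]))
    if (length(bad))
      stop(sprintf("%s: invalid value in column '%s' at data line %d",
                   path, col, bad[1] + 1L))
  }
  d
}

#' Read and validate a cohort table
#'
#' Expects columns `id`, `severity` (0-100), `rhythm_perception`,
#' `rhythm_sync` (0-1) and the three `ctenv_*` columns as written by
#' [write_table_csv()]; ids must be unique. Errors name the offending
#' column and line.
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
read_cohort_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d <- check_schema(d, list(
    id = function(x) !is.na(x) & nzchar(x),
    severity = function(x) is.finite(x) & x >= 0 & x <= 100,
    rhythm_perception = is.finite,
    rhythm_sync = function(x) is.finite(x) & x >= 0 & x <= 1,
    ctenv_delta = is.finite, ctenv_theta = is.finite,
    ctenv_alpha = is.finite), path)
  if (anyDuplicated(d$id))
    stop(sprintf("%s: duplicate participant id '%s'", path,
                 d$id[anyDuplicated(d$id)]))
  d
}

#' Read and validate trial-level treatment records
#'
#' Expects columns `participant`, `item`, `session`, `condition`,
#' `n_correct_words`, `n_words`; enforces
#' `0 <= n_correct_words <= n_words` and positive integer sessions, with
#' line-numbered errors.
#'
#' @param path CSV path.
#' @return validated data.frame.
#' @export
read_trials_csv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d <- check_schema(d, list(
    participant = function(x) !is.na(x) & nzchar(as.character(x)),
    item = function(x) !is.na(x),
    session = function(x) is.finite(x) & x >= 1 & x == round(x),
    condition = function(x) !is.na(x) & nzchar(x),
    n_words = function(x) is.finite(x) & x >= 1 & x == round(x),
    n_correct_words = function(x) is.finite(x) & x >= 0 & x == round(x)),
    path)
  bad <- which(d$n_correct_words > d$n_words)
  if (length(bad))
    stop(sprintf("%s: n_correct_words > n_words at data line %d", path,
                 bad[1] + 1L))
  d
}

#' Bundled nine-participant aphasia cohort demographics
#'
#' The demographic and behavioral summary table of the nine-participant
#' Spanish-speaking post-stroke aphasia cohort around which the pipeline's
#' simulation defaults are calibrated: months post-onset (MPO), age,
#' aphasia severity (WAB-AQ aphasia quotient, 0-100), beat-perception
#' ability (CA-BAT) and beat-synchronization score (BAT-sync, 0-1).
#'
#' @return data.frame with one row per participant.
#' @export
reference_cohort <- function() {
  utils::read.csv(system.file("extdata", "aphasia_cohort_demographics.csv",
                              package = "ctenvr"),
                  stringsAsFactors = FALSE)
}

#' Descriptive statistics of a cohort demographics table
#'
#' Column means and SDs of the numeric demographic columns, rounded to one
#' decimal as conventionally reported in cohort tables.
#'
#' @param cohort data.frame as returned by [reference_cohort()].
#' @param digits decimals to round to (default 1).
#' @return data.frame with rows `mean` and `sd`.
#' @export
cohort_descriptives <- function(cohort, digits = 1) {
  num <- cohort[vapply(cohort, is.numeric, logical(1))]
  out <- rbind(mean = vapply(num, mean, numeric(1)),
               sd = vapply(num, stats::sd, numeric(1)))
  round(out, digits)
}
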