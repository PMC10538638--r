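#' Construct a continuous multichannel EEG recording
#'
#' The basic container for continuous EEG: a channels-by-samples numeric
#' matrix in microvolts with a sampling rate, channel labels, the current
#' reference, and a band label that tracks which spectral content the data
#' carry (`"broadband"` until [extract_band()] is applied).
#'
#' @param data numeric matrix, channels x samples, in microvolts.
#' @param rate sampling rate in Hz (> 0).
#' @param channel_labels character vector, one label per row of `data`.
#' @param reference current reference: a channel label, `"Cz"`-style online
#'   reference, or `"mastoid-average"` after [rereference_mastoids()].
#' @param band one of `"broadband"`, `"delta"`, `"theta"`, `"alpha"`.
#' @return an object of class `eeg_recording`.
#' @export
eeg_recording <- function(data, rate, channel_labels,
                          reference = "Cz", band = "broadband") {
  data <- as.matrix(data)
  if (!is.numeric(data)) stop("`data` must be a numeric matrix")
  if (length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("`rate` must be a single positive number (Hz)")
  if (length(channel_labels) != nrow(data))
    stop(sprintf("channel label count (%d) must equal channel row count (%d)",
                 length(channel_labels), nrow(data)))
  band <- match.arg(band, c("broadband", "delta", "theta", "alpha"))
  structure(
    list(data = data, rate = rate,
         channel_labels = as.character(channel_labels),
         reference = reference, band = band),
    class = "eeg_recording"
  )
}

#' @export
print.eeg_recording <- function(x, ...) {
  cat(sprintf(
    "<eeg_recording> %d channels x %d samples @ %g Hz (%.1f s)\n  reference: %s | band: %s\n",
    nrow(x$data), ncol(x$data), x$rate, ncol(x$data) / x$rate,
    x$reference, x$band))
  invisible(x)
}

#' @export
dim.eeg_recording <- function(x) dim(x$data)

n_samples <- function(x) ncol(x$data)

#' Construct an epoched EEG object
#'
#' A list of fixed-length epochs sharing channel order, rate, and length,
#' cut relative to stimulus onsets (see [epoch_segments()]).
#'
#' @param epochs list of channels x samples matrices of identical shape.
#' @param rate sampling rate in Hz.
#' @param channel_labels channel labels common to all epochs.
#' @param window length-2 numeric, epoch window in seconds relative to onset.
#' @param reference,band carried over from the source recording.
#' @return an object of class `epoched_eeg`.
#' @export
epoched_eeg <- function(epochs, rate, channel_labels, window,
                        reference = "Cz", band = "broadband") {
  if (!length(epochs)) stop("`epochs` must contain at least one epoch")
  shapes <- vapply(epochs, dim, integer(2))
  if (any(shapes[1, ] != shapes[1, 1]) || any(shapes[2, ] != shapes[2, 1]))
    stop("all epochs must share the same channels x samples shape")
  if (shapes[1, 1] != length(channel_labels))
    stop("channel labels must match epoch row count")
  structure(
    list(epochs = epochs, rate = rate,
         channel_labels = as.character(channel_labels),
         window = window, reference = reference, band = band),
    class = "epoched_eeg"
  )
}

#' @export
print.epoched_eeg <- function(x, ...) {
  cat(sprintf(
    "<epoched_eeg> %d epochs, %d channels x %d samples @ %g Hz, window [%g, %g] s, band %s\n",
    length(x$epochs), nrow(x$epochs[[1]]), ncol(x$epochs[[1]]), x$rate,
    x$window[1], x$window[2], x$band))
  invisible(x)
}

#' @export
length.epoched_eeg <- function(x) length(x$epochs)

#' Construct a speech envelope time series
#'
#' Nonnegative amplitude-envelope samples at a given rate; the regressor for
#' forward TRF models.
#'
#' @param samples numeric vector of nonnegative amplitudes.
#' @param rate sampling rate in Hz.
#' @return an object of class `speech_envelope`.
#' @export
speech_envelope <- function(samples, rate) {
  samples <- as.numeric(samples)
  if (length(rate) != 1L || !is.finite(rate) || rate <= 0)
    stop("`rate` must be a single positive number (Hz)")
  if (any(!is.finite(samples))) stop("envelope samples must be finite")
  if (any(samples < -1e-12)) stop("envelope samples must be nonnegative")
  samples[samples < 0] <- 0
  structure(list(samples = samples, rate = rate,
                 duration = length(samples) / rate),
            class = "speech_envelope")
}

#' @export
print.speech_envelope <- function(x, ...) {
  cat(sprintf("<speech_envelope> %d samples @ %g Hz (%.2f s), mean %.3g\n",
              length(x$samples), x$rate, x$duration, mean(x$samples)))
  invisible(x)
}

#' @export
length.speech_envelope <- function(x) length(x$samples)
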