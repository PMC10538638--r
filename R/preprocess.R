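#' Resample a recording to a lower rate
#'
#' Fourier-domain resampling (spectrum truncated at the new Nyquist, an
#' ideal anti-alias filter), used to bring clinical-rate EEG (e.g.
#' 5000 Hz) down to the 128 Hz analysis rate. Only downsampling is
#' supported; duration is preserved within one sample.
#'
#' @param recording an [eeg_recording].
#' @param target_rate new sampling rate in Hz (`<=` native rate).
#' @return an [eeg_recording] at `target_rate`.
#' @export
resample_to <- function(recording, target_rate) {
  if (target_rate > recording$rate)
    stop(sprintf("upsampling (%g -> %g Hz) is not supported",
                 recording$rate, target_rate))
  if (target_rate == recording$rate) return(recording)
  n_out <- as.integer(round(n_samples(recording) *
                              target_rate / recording$rate))
  data <- apply_by_channel(recording$data, function(x)
    fft_resample(x, n_out))
  eeg_recording(data, target_rate, recording$channel_labels,
                reference = recording$reference, band = recording$band)
}

#' Band-limit a recording with windowed-sinc FIR filters
#'
#' Applies a high-pass and a low-pass linear-phase windowed-sinc FIR filter
#' (Hamming window) of the given orders, with group-delay compensation and
#' 2 s reflection padding. Defaults follow a 1-15 Hz analysis band
#' (high-pass 1 Hz, order 846; low-pass 15 Hz, order 212); the delta path
#' uses `hp_cutoff = 0.75` with the same orders.
#'
#' @param recording an [eeg_recording].
#' @param hp_cutoff,hp_order high-pass cutoff (Hz) and FIR order; `NULL`
#'   cutoff skips the high-pass.
#' @param lp_cutoff,lp_order low-pass cutoff (Hz) and FIR order; `NULL`
#'   cutoff skips the low-pass.
#' @return the filtered [eeg_recording].
#' @export
sinc_filter <- function(recording, hp_cutoff = 1, hp_order = 846,
                        lp_cutoff = 15, lp_order = 212) {
  nyq <- recording$rate / 2
  for (co in c(hp_cutoff, lp_cutoff))
    if (!is.null(co) && (co <= 0 || co >= nyq))
      stop(sprintf("cutoff %g Hz outside (0, Nyquist = %g Hz)", co, nyq))
  data <- recording$data
  if (!is.null(hp_cutoff))
    data <- apply_by_channel(data, function(x)
      fir_filter_compensated(x, hp_order, hp_cutoff / nyq, "high",
                             recording$rate))
  if (!is.null(lp_cutoff))
    data <- apply_by_channel(data, function(x)
      fir_filter_compensated(x, lp_order, lp_cutoff / nyq, "low",
                             recording$rate))
  eeg_recording(data, recording$rate, recording$channel_labels,
                reference = recording$reference, band = recording$band)
}

#' Re-reference to the average of the two mastoids
#'
#' Subtracts the mean of the `M1`/`M2` channels from every channel and marks
#' the recording as mastoid-referenced. Applying it twice is an error; the
#' subtracted mastoid-mean trace is stored so the operation is invertible.
#'
#' @param recording an [eeg_recording] containing both mastoid channels.
#' @return the re-referenced [eeg_recording], with attribute
#'   `"mastoid_mean"` holding the subtracted trace.
#' @export
rereference_mastoids <- function(recording) {
  if (identical(recording$reference, "mastoid-average"))
    stop("recording is already mastoid-referenced")
  m <- mastoid_labels()
  missing <- setdiff(m, recording$channel_labels)
  if (length(missing))
    stop(sprintf("mastoid channel(s) missing from recording: %s",
                 paste(missing, collapse = ", ")))
  idx <- match(m, recording$channel_labels)
  mast_mean <- colMeans(recording$data[idx, , drop = FALSE])
  data <- sweep(recording$data, 2L, mast_mean, "-")
  out <- eeg_recording(data, recording$rate, recording$channel_labels,
                       reference = "mastoid-average", band = recording$band)
  attr(out, "mastoid_mean") <- mast_mean
  out
}

#' Cut a continuous recording into onset-locked epochs
#'
#' One epoch per stimulus onset, spanning `[tmin, tmax]` seconds around it
#' (default -5 to 70 s, covering a 1-min speech segment with pre-roll that
#' also buffers filter edges).
#'
#' @param recording an [eeg_recording].
#' @param onsets numeric vector of onset times in seconds.
#' @param tmin,tmax epoch window in seconds relative to each onset.
#' @return an [epoched_eeg] with `length(onsets)` epochs of
#'   `round((tmax - tmin) * rate)` samples.
#' @export
epoch_segments <- function(recording, onsets, tmin = -5, tmax = 70) {
  if (tmin >= tmax) stop("`tmin` must be smaller than `tmax`")
  rate <- recording$rate
  n <- n_samples(recording)
  len <- as.integer(round((tmax - tmin) * rate))
  epochs <- lapply(onsets, function(on) {
    start <- as.integer(round((on + tmin) * rate)) + 1L
    if (start < 1L || start + len - 1L > n)
      stop(sprintf(
        "epoch [%g, %g] s around onset %g s falls outside the recording (0-%g s)",
        on + tmin, on + tmax, on, n / rate))
    recording$data[, start:(start + len - 1L), drop = FALSE]
  })
  epoched_eeg(epochs, rate, recording$channel_labels, window = c(tmin, tmax),
              reference = recording$reference, band = recording$band)
}

#' Extract a canonical EEG band from broadband epochs
#'
#' Third-order Butterworth filtering, applied zero-phase (forward-backward)
#' so band-dependent group delay cannot distort TRF latencies: theta is a
#' 4-8 Hz band-pass, alpha an 8-15 Hz band-pass, and delta a 4 Hz low-pass
#' — the delta path assumes its input came through the 0.75 Hz high-pass
#' variant of [sinc_filter()], yielding an effective 0.75-4 Hz band.
#'
#' @param epochs a broadband [epoched_eeg].
#' @param band one of `"delta"`, `"theta"`, `"alpha"`.
#' @return an [epoched_eeg] with the band label set.
#' @export
extract_band <- function(epochs, band) {
  band <- match.arg(band, c("delta", "theta", "alpha"))
  if (!identical(epochs$band, "broadband"))
    stop(sprintf("band extraction requires broadband input (got '%s')",
                 epochs$band))
  rate <- epochs$rate
  nyq <- rate / 2
  filt <- switch(band,
    delta = function(x) butter_filtfilt(x, 3, 4 / nyq, "low", rate),
    theta = function(x) butter_filtfilt(x, 3, c(4, 8) / nyq, "pass", rate),
    alpha = function(x) butter_filtfilt(x, 3, c(8, 15) / nyq, "pass", rate)
  )
  out <- lapply(epochs$epochs, function(e) apply_by_channel(e, filt))
  epoched_eeg(out, rate, epochs$channel_labels, window = epochs$window,
              reference = epochs$reference, band = band)
}

#' Reject high-amplitude artifact windows
#'
#' Desk-scale artifact handling: any 1-s window containing a sample whose
#' absolute amplitude exceeds `amplitude_threshold` is zeroed out
#' (zero-weighted for the regression stages) and logged. This replaces
#' subspace-reconstruction and ICA cleaning with a transparent, testable
#' rule.
#'
#' @param epochs an [epoched_eeg].
#' @param amplitude_threshold rejection threshold in microvolts (> 0).
#' @param strict logical; if rejections exceed 50% of the data, escalate the
#'   warning to an error.
#' @return the cleaned [epoched_eeg]; attribute `"rejection_log"` is a list
#'   with the total window count, rejected count, and per-epoch rejected
#'   window indices.
#' @export
reject_artifacts <- function(epochs, amplitude_threshold = 500,
                             strict = FALSE) {
  if (amplitude_threshold <= 0) stop("`amplitude_threshold` must be > 0")
  rate <- epochs$rate
  win <- max(1L, as.integer(round(rate)))
  n_rej <- 0L; n_tot <- 0L
  log_idx <- vector("list", length(epochs$epochs))
  cleaned <- epochs$epochs
  for (i in seq_along(cleaned)) {
    e <- cleaned[[i]]
    n_win <- ceiling(ncol(e) / win)
    n_tot <- n_tot + n_win
    bad <- integer(0)
    for (w in seq_len(n_win)) {
      cols <- ((w - 1L) * win + 1L):min(w * win, ncol(e))
      if (any(abs(e[, cols]) > amplitude_threshold)) {
        e[, cols] <- 0
        bad <- c(bad, w)
      }
    }
    n_rej <- n_rej + length(bad)
    log_idx[[i]] <- bad
    cleaned[[i]] <- e
  }
  if (n_rej > 0.5 * n_tot) {
    msg <- sprintf("artifact rejection removed %d of %d windows (> 50%%)",
                   n_rej, n_tot)
    if (strict) stop(msg) else warning(msg)
  }
  out <- epoched_eeg(cleaned, rate, epochs$channel_labels,
                     window = epochs$window, reference = epochs$reference,
                     band = epochs$band)
  attr(out, "rejection_log") <- list(
    threshold_uv = amplitude_threshold,
    n_windows = n_tot, n_rejected = n_rej,
    rejected_windows = log_idx)
  out
}

#' Trial-averaged auditory evoked response with N1 detection
#'
#' Averages stimulus-locked trials, subtracts the pre-stimulus baseline
#' mean, and reports the most negative deflection within the N1 search
#' window (50-250 ms by default) on the channel-averaged waveform — the
#' auditory long-latency response used to verify that auditory stimulation
#' reached cortex. The response is flagged unreliable when the N1 amplitude
#' does not clear the baseline noise floor (baseline SD scaled by a
#' Bonferroni-corrected normal quantile, since the peak is the minimum over
#' the whole search window).
#'
#' @param recording an [eeg_recording].
#' @param event_times stimulus onset times in seconds (>= 1 event).
#' @param window trial window in seconds relative to onset.
#' @param n1_search latency window (s) in which to search for the N1.
#' @return list of class `evoked_response`: `waveform` (channels x samples,
#'   baseline-corrected mean), `times`, `n_trials`, `peaks` (data.frame with
#'   latency, amplitude, polarity), `reliable`.
#' @export
evoked_average <- function(recording, event_times, window = c(-0.2, 0.5),
                           n1_search = c(0.05, 0.25)) {
  if (!length(event_times)) stop("at least one event is required")
  rate <- recording$rate
  len <- as.integer(round((window[2] - window[1]) * rate))
  times <- window[1] + (seq_len(len) - 1L) / rate
  acc <- matrix(0, nrow(recording$data), len)
  n_used <- 0L
  for (on in event_times) {
    start <- as.integer(round((on + window[1]) * rate)) + 1L
    if (start < 1L || start + len - 1L > n_samples(recording)) next
    acc <- acc + recording$data[, start:(start + len - 1L), drop = FALSE]
    n_used <- n_used + 1L
  }
  if (n_used == 0L) stop("no event window fits inside the recording")
  avg <- acc / n_used
  base_cols <- times < 0
  if (any(base_cols)) {
    avg <- avg - rowMeans(avg[, base_cols, drop = FALSE])
    base_sd <- stats::sd(colMeans(avg)[base_cols])
  } else base_sd <- NA_real_
  gm <- colMeans(avg)
  search <- times >= n1_search[1] & times <= n1_search[2]
  i_min <- which(search)[which.min(gm[search])]
  n1_amp <- gm[i_min]; n1_lat <- times[i_min]
  # picking the minimum over the search window is an extreme-value
  # selection, so the noise floor is compared Bonferroni-corrected
  crit <- stats::qnorm(1 - 0.005 / sum(search))
  reliable <- is.finite(base_sd) && abs(n1_amp) > crit * base_sd
  structure(list(
    waveform = avg, times = times, n_trials = n_used,
    peaks = data.frame(component = "N1", latency = n1_lat,
                       amplitude = n1_amp, polarity = "negative"),
    baseline_sd = base_sd, reliable = reliable),
    class = "evoked_response")
}

#' @export
print.evoked_response <- function(x, ...) {
  cat(sprintf(
    "<evoked_response> %d trials; N1 %.2f uV at %.0f ms (%s)\n",
    x$n_trials, x$peaks$amplitude[1], 1000 * x$peaks$latency[1],
    if (isTRUE(x$reliable)) "reliable" else "unreliable"))
  invisible(x)
}
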