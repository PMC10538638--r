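#' Multiband Hilbert amplitude envelope of stimulus audio
#'
#' Computes the broadband temporal envelope the way auditory TRF studies do:
#' the audio is split into `n_bands` band-pass channels spaced
#' logarithmically between `f_lo` and `f_hi` (a cochlear-inspired
#' filterbank), the analytic amplitude of each band is taken via the Hilbert
#' transform, the band envelopes are averaged (unweighted), and the result
#' is low-pass filtered and resampled to the EEG analysis rate.
#'
#' @param audio numeric waveform vector.
#' @param rate audio sampling rate in Hz.
#' @param n_bands number of filterbank bands (>= 1; default 8).
#' @param f_lo,f_hi filterbank edges in Hz (`f_lo < f_hi < rate/2`);
#'   `f_hi` defaults to `min(8000, 0.9 * rate/2)`.
#' @param out_rate output envelope rate in Hz (default 128, the EEG rate).
#' @param lp_cutoff envelope low-pass cutoff in Hz before resampling.
#' @param compression optional power-law exponent (e.g. 0.3) applied to each
#'   band envelope; `NULL` (default) applies none.
#' @return a [speech_envelope] at `out_rate`.
#' @export
multiband_envelope <- function(audio, rate, n_bands = 8, f_lo = 80,
                               f_hi = NULL, out_rate = 128, lp_cutoff = 32,
                               compression = NULL) {
  if (n_bands < 1) stop("`n_bands` must be >= 1")
  nyq <- rate / 2
  if (is.null(f_hi)) f_hi <- min(8000, 0.9 * nyq)
  if (!(f_lo < f_hi && f_hi < nyq))
    stop(sprintf("need f_lo < f_hi < Nyquist (%g Hz)", nyq))
  audio <- as.numeric(audio)
  n_out <- max(1L, as.integer(round(length(audio) / rate * out_rate)))
  if (all(audio == 0)) {
    warning("silent (all-zero) audio; returning a zero envelope")
    return(speech_envelope(numeric(n_out), out_rate))
  }
  edges <- exp(seq(log(f_lo), log(f_hi), length.out = n_bands + 1))
  acc <- numeric(length(audio))
  for (b in seq_len(n_bands)) {
    x <- butter_filtfilt(audio, 4, c(edges[b], edges[b + 1]) / nyq, "pass",
                         rate)
    env_b <- Mod(analytic_signal(x))
    if (!is.null(compression)) env_b <- env_b^compression
    acc <- acc + env_b
  }
  env <- acc / n_bands
  if (lp_cutoff < nyq)
    env <- butter_filtfilt(env, 3, lp_cutoff / nyq, "low", rate)
  if (out_rate != rate) env <- fft_resample(env, n_out)
  env[env < 0] <- 0  # resampling ripple can dip below zero
  speech_envelope(env, out_rate)
}

#' Align an envelope to an EEG time axis
#'
#' Resamples the envelope to the EEG rate and truncates or zero-pads it to
#' exactly `n_samples`, recording what was done. A shortfall longer than 1 s
#' indicates a misaligned stimulus and is an error.
#'
#' @param envelope a [speech_envelope].
#' @param eeg_rate target rate in Hz.
#' @param n_samples required length in samples at `eeg_rate`.
#' @return a [speech_envelope] of exactly `n_samples` samples; attribute
#'   `"alignment"` records the samples trimmed or padded.
#' @export
align_envelope <- function(envelope, eeg_rate, n_samples) {
  x <- envelope$samples
  if (eeg_rate != envelope$rate) {
    x <- fft_resample(x, as.integer(round(length(x) * eeg_rate /
                                            envelope$rate)))
    x[x < 0] <- 0
  }
  shortfall <- n_samples - length(x)
  if (shortfall > eeg_rate)
    stop(sprintf("envelope is %.2f s shorter than the EEG segment",
                 shortfall / eeg_rate))
  if (shortfall > 0) {
    x <- c(x, numeric(shortfall))
  } else if (shortfall < 0) {
    x <- x[seq_len(n_samples)]
  }
  out <- speech_envelope(x, eeg_rate)
  attr(out, "alignment") <- list(padded = max(shortfall, 0L),
                                 trimmed = max(-shortfall, 0L))
  out
}
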