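#' Generate a ground-truth multichannel TRF kernel
#'
#' Builds a biphasic kernel with auditory-evoked (N1/P2-like) morphology: a
#' negative Gaussian lobe near 100 ms followed by a positive lobe near
#' 220 ms, with amplitude varying smoothly across channels to mimic a scalp
#' field that is strongest over fronto-central sites. Used as known ground
#' truth in TRF parameter-recovery tests and simulations.
#'
#' @param channel_labels character vector of channel names (nonempty).
#' @param lag_min,lag_max kernel support window in seconds (`lag_min < lag_max`).
#' @param rate sampling rate in Hz.
#' @param peak_latencies length-2 numeric: latencies (s) of the negative and
#'   positive lobe.
#' @param peak_widths length-2 numeric: Gaussian SDs (s) of the two lobes.
#' @param amplitude overall kernel scale (a.u. per envelope unit); 0 gives an
#'   all-zero kernel.
#' @param seed integer seed for the smooth channel-to-channel amplitude
#'   variation.
#' @return a `trf_kernel`: list with `weights` (channels x lags), `lag_axis`
#'   (s), `rate`, and `channel_labels`.
#' @export
generate_trf_kernel <- function(channel_labels = standard_montage(),
                                lag_min = -0.1, lag_max = 0.65, rate = 128,
                                peak_latencies = c(0.10, 0.22),
                                peak_widths = c(0.03, 0.05),
                                amplitude = 1, seed = 1L) {
  if (!length(channel_labels)) stop("`channel_labels` must be nonempty")
  if (lag_min >= lag_max) stop("`lag_min` must be smaller than `lag_max`")
  lag_idx <- seq.int(round(lag_min * rate), round(lag_max * rate))
  lag_axis <- lag_idx / rate
  n_ch <- length(channel_labels)
  # smooth scalp gradient: strongest centrally, tapering to the edges,
  # with a small seeded per-channel perturbation smoothed over neighbours
  base <- 0.5 + 0.5 * cos(seq(-pi / 2, pi / 2, length.out = n_ch))
  jitter <- with_seed(seed, stats::rnorm(n_ch, sd = 0.1))
  if (n_ch >= 3) jitter <- stats::filter(jitter, rep(1 / 3, 3), sides = 2)
  jitter[is.na(jitter)] <- 0
  ch_amp <- pmax(base + as.numeric(jitter), 0.05)
  shape <- -dnorm_s(lag_axis, peak_latencies[1], peak_widths[1]) +
    0.7 * dnorm_s(lag_axis, peak_latencies[2], peak_widths[2])
  # cosine taper keeps the support strictly inside [lag_min, lag_max]
  taper <- 0.5 - 0.5 * cos(2 * pi * seq(0, 1, length.out = length(lag_axis)))
  shape <- shape * taper
  weights <- amplitude * outer(ch_amp, shape)
  rownames(weights) <- channel_labels
  structure(list(weights = weights, lag_axis = lag_axis, rate = rate,
                 channel_labels = as.character(channel_labels)),
            class = "trf_kernel")
}

# unit-peak Gaussian bump
dnorm_s <- function(x, mu, sd) exp(-0.5 * ((x - mu) / sd)^2)

#' @export
print.trf_kernel <- function(x, ...) {
  cat(sprintf("<trf_kernel> %d channels x %d lags @ %g Hz, lags [%g, %g] s\n",
              nrow(x$weights), ncol(x$weights), x$rate,
              min(x$lag_axis), max(x$lag_axis)))
  invisible(x)
}

#' Convolve an envelope with a multichannel TRF kernel
#'
#' Computes the noiseless forward-model response
#' `y_c(t) = sum_j w_c(j) * s(t - lag_j)` for every channel, with zero
#' padding outside the stimulus.
#'
#' @param envelope a [speech_envelope].
#' @param kernel a `trf_kernel` at the same rate.
#' @return channels x samples numeric matrix.
#' @export
convolve_kernel <- function(envelope, kernel) {
  if (abs(envelope$rate - kernel$rate) > 1e-9)
    stop(sprintf("envelope rate (%g Hz) does not match kernel rate (%g Hz)",
                 envelope$rate, kernel$rate))
  X <- lagged_matrix(envelope$samples, round(kernel$lag_axis * kernel$rate))
  out <- tcrossprod(kernel$weights, X)  # channels x samples
  rownames(out) <- kernel$channel_labels
  out
}

#' Synthesize continuous EEG as envelope * kernel plus 1/f noise
#'
#' The generative mirror of the forward TRF model: each channel is the
#' stimulus envelope convolved with that channel's kernel row, plus additive
#' `1/f^noise_exponent` noise scaled so that the ratio of signal variance to
#' noise variance — after band-limiting both to the 1-15 Hz analysis band —
#' equals the requested SNR.
#'
#' @param envelope a [speech_envelope].
#' @param kernel a `trf_kernel` at the same rate.
#' @param snr_db signal-to-noise ratio in dB within 1-15 Hz. `Inf` adds no
#'   noise; `-Inf` scales the signal to zero, leaving noise only.
#' @param noise_exponent spectral exponent of the background noise
#'   (1 = pink, 0 = white).
#' @param seed integer seed.
#' @return an [eeg_recording] with reference `"Cz"` and band `"broadband"`.
#' @export
synthesize_eeg <- function(envelope, kernel, snr_db = 0, noise_exponent = 1,
                           seed = 1L) {
  if (abs(envelope$rate - kernel$rate) > 1e-9)
    stop(sprintf("envelope rate (%g Hz) does not match kernel rate (%g Hz)",
                 envelope$rate, kernel$rate))
  rate <- envelope$rate
  sig <- convolve_kernel(envelope, kernel)
  n_ch <- nrow(sig); n <- ncol(sig)
  noise <- with_seed(seed, {
    t(vapply(seq_len(n_ch),
             function(i) one_over_f_noise(n, noise_exponent, rate),
             numeric(n)))
  })
  if (identical(snr_db, Inf)) {
    data <- sig
  } else if (identical(snr_db, -Inf)) {
    data <- noise
  } else {
    band_var <- function(m) {
      hi <- min(15, rate / 2 * 0.95)
      v <- apply(m, 1L, function(x)
        stats::var(butter_filtfilt(x, 3, c(1, hi) / (rate / 2), "pass", rate)))
      pmax(v, .Machine$double.eps)
    }
    target <- 10^(snr_db / 10)
    sig_var <- apply(sig, 1L, stats::var)
    scale <- ifelse(sig_var > 0,
                    sqrt(band_var(sig) / (target * band_var(noise))),
                    1)  # zero-signal channels keep unit-variance noise
    data <- sig + noise * scale
  }
  rownames(data) <- kernel$channel_labels
  eeg_recording(data, rate, kernel$channel_labels,
                reference = "Cz", band = "broadband")
}

# time x lags matrix of x shifted by integer lags (in samples); column j
# holds x[t - lag_j], zero outside the recording
lagged_matrix <- function(x, lag_idx) {
  n <- length(x)
  out <- matrix(0, n, length(lag_idx))
  for (j in seq_along(lag_idx)) {
    k <- lag_idx[j]
    src <- seq_len(n) - k
    ok <- src >= 1L & src <= n
    out[ok, j] <- x[src[ok]]
  }
  out
}
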