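# Internal filtering helpers shared by preprocessing and envelope extraction.
#
# All user-facing filters reflect-pad the signal (2 s by default) before
# filtering to suppress edge transients, and compensate FIR group delay so
# filtered signals stay aligned with the stimulus time axis.

#' Analytic signal via the frequency-domain Hilbert transform
#'
#' @param x numeric vector.
#' @return complex vector; `Mod()` of it is the instantaneous amplitude.
#' @keywords internal
analytic_signal <- function(x) {
  n <- length(x)
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) {
    h[1] <- 1; h[n / 2 + 1] <- 1
    h[2:(n / 2)] <- 2
  } else {
    h[1] <- 1
    h[2:((n + 1) / 2)] <- 2
  }
  stats::fft(X * h, inverse = TRUE) / n
}

reflect_pad <- function(x, n_pad) {
  n <- length(x)
  n_pad <- min(n_pad, n - 1L)
  c(rev(x[2:(n_pad + 1L)]), x, rev(x[(n - n_pad):(n - 1L)]))
}

# Zero-phase (forward-backward) Butterworth on one vector with reflection
# padding; `w` in normalized frequency as for signal::butter.
butter_filtfilt <- function(x, order, w, type, rate, pad_s = 2) {
  bf <- signal::butter(order, w, type = type)
  n_pad <- as.integer(round(pad_s * rate))
  xp <- reflect_pad(x, n_pad)
  yp <- signal::filtfilt(bf, xp)
  n_pad <- min(n_pad, length(x) - 1L)
  yp[(n_pad + 1L):(n_pad + length(x))]
}

# Linear-phase windowed-sinc FIR (Hamming, via signal::fir1) applied causally
# and then advanced by the group delay (order/2 samples) to restore alignment.
fir_filter_compensated <- function(x, order, w, type, rate, pad_s = 2) {
  if (order %% 2 != 0) order <- order + 1L  # even order -> integer group delay
  if (length(x) <= order)
    stop(sprintf("filter order %d incompatible with signal length %d",
                 order, length(x)))
  h <- as.numeric(signal::fir1(order, w, type = type))
  delay <- order / 2L
  n_pad <- as.integer(round(pad_s * rate)) + delay
  xp <- reflect_pad(x, n_pad)
  yp <- stats::filter(xp, h, method = "convolution", sides = 1)
  n_pad_eff <- min(n_pad, length(x) - 1L)
  start <- n_pad_eff + delay + 1L
  out <- yp[start:(start + length(x) - 1L)]
  as.numeric(out)
}

apply_by_channel <- function(data, fun) {
  out <- t(apply(data, 1L, fun))
  dimnames(out) <- dimnames(data)
  out
}

# Fourier-domain resampling: the spectrum is truncated (or zero-padded) at
# the new Nyquist, which is an ideal anti-alias filter for band-limited
# signals (the same scheme as scipy.signal.resample).
fft_resample <- function(x, n_out) {
  n <- length(x)
  if (n_out == n) return(x)
  X <- stats::fft(x)
  keep <- min(n, n_out)
  half <- floor((keep - 1) / 2)
  Y <- complex(real = numeric(n_out))
  Y[1] <- X[1]
  if (half > 0) {
    Y[2:(half + 1)] <- X[2:(half + 1)]
    Y[(n_out - half + 1):n_out] <- X[(n - half + 1):n]
  }
  if (keep %% 2 == 0) {  # split the shared Nyquist bin
    ny <- keep / 2 + 1
    if (n_out < n) {
      Y[ny] <- 2 * Re(X[ny])  # fold conjugate halves onto one bin
    } else {
      Y[ny] <- X[ny] / 2
      Y[n_out - keep / 2 + 1] <- Conj(X[ny]) / 2
    }
  }
  Re(stats::fft(Y, inverse = TRUE)) * (1 / n)
}

# 1/f^alpha noise generated by shaping white Gaussian noise in the Fourier
# domain; unit variance on output (alpha = 0 gives white noise).
one_over_f_noise <- function(n, alpha = 1, rate = 1) {
  white <- stats::rnorm(n)
  if (alpha == 0) return(white)
  X <- stats::fft(white)
  freqs <- c(0, seq_len(n - 1)) / n * rate
  # fold to physical frequencies
  freqs <- pmin(freqs, rate - freqs)
  gain <- c(0, 1 / (freqs[-1]^(alpha / 2)))
  x <- Re(stats::fft(X * gain, inverse = TRUE) / n)
  x / stats::sd(x)
}
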