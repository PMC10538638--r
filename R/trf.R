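#' Build a time-lagged design matrix from a stimulus envelope
#'
#' Column `j` holds the envelope shifted by `lag_axis[j]`, so a forward TRF
#' `w` predicts the response as `y(t) = sum_j w_j * s(t - lag_j)`. Lag
#' indices are `round(lag * rate)` with inclusive endpoints (at 128 Hz the
#' default -100 to 650 ms window gives 97 lags); samples falling outside the
#' recording are zero-filled.
#'
#' @param stimulus a [speech_envelope] (or numeric vector with `rate`).
#' @param lag_min,lag_max lag window in seconds (`lag_min < lag_max`).
#' @param rate sampling rate, required only when `stimulus` is a bare vector.
#' @return list of class `lagged_design`: `matrix` (time x lags),
#'   `lag_axis` (s), `lag_idx` (samples), `rate`.
#' @export
build_lagged_design <- function(stimulus, lag_min = -0.1, lag_max = 0.65,
                                rate = NULL) {
  if (inherits(stimulus, "speech_envelope")) {
    x <- stimulus$samples
    rate <- stimulus$rate
  } else {
    if (is.null(rate)) stop("`rate` is required for a bare stimulus vector")
    x <- as.numeric(stimulus)
  }
  if (lag_min >= lag_max) stop("`lag_min` must be smaller than `lag_max`")
  lag_idx <- seq.int(round(lag_min * rate), round(lag_max * rate))
  structure(list(matrix = lagged_matrix(x, lag_idx),
                 lag_axis = lag_idx / rate, lag_idx = lag_idx, rate = rate),
            class = "lagged_design")
}

# penalty scale: mean eigenvalue of X'X, making the 2^0..2^20 grid scale-free
penalty_scale <- function(XtX) sum(diag(XtX)) / ncol(XtX)

#' Fit a single-channel TRF by ridge regression
#'
#' Solves the penalized least-squares problem
#' `w = (X'X + lambda * m * I)^{-1} X'y` on column-centered data, where `m`
#' is the mean eigenvalue of `X'X`; this normalization makes the integer
#' powers-of-two lambda grid scale-free. The intercept is recovered from
#' the centering means.
#'
#' @param design a `lagged_design` from [build_lagged_design()].
#' @param response numeric response vector, same length as the design rows.
#' @param lambda ridge weight (>= 0; 0 requires a well-conditioned design).
#' @return list of class `trf_model`: `weights` (1 x lags matrix),
#'   `intercept`, `lambda`, `lag_axis`, `rate`.
#' @export
fit_ridge <- function(design, response, lambda) {
  X <- design$matrix
  y <- as.numeric(response)
  if (nrow(X) != length(y))
    stop("design rows must equal response length")
  if (lambda < 0) stop("`lambda` must be >= 0")
  xm <- colMeans(X); ym <- mean(y)
  Xc <- sweep(X, 2L, xm, "-")
  XtX <- crossprod(Xc)
  pen <- lambda * penalty_scale(XtX)
  A <- XtX + diag(pen, ncol(XtX))
  w <- tryCatch(solve(A, crossprod(Xc, y - ym)),
                error = function(e)
                  stop("ridge system is singular; use lambda > 0",
                       call. = FALSE))
  weights <- matrix(w, nrow = 1, dimnames = list(NULL, NULL))
  structure(list(weights = weights,
                 intercept = ym - sum(xm * w),
                 lambda = lambda, lag_axis = design$lag_axis,
                 rate = design$rate),
            class = "trf_model")
}

#' @export
print.trf_model <- function(x, ...) {
  cat(sprintf("<trf_model> %d channels x %d lags, lambda = %g\n",
              nrow(x$weights), ncol(x$weights), x$lambda))
  invisible(x)
}

#' Predict EEG from a TRF model and score the fit
#'
#' Convolves the stimulus with the model weights and returns the Pearson
#' correlation between predicted and observed response per channel — the
#' CTenv estimate for that data. Correlations are computed over the valid
#' (unpadded) samples only; a zero-variance prediction or response yields
#' `r = 0` with a warning so summaries never propagate `NaN`.
#'
#' @param model a `trf_model` (possibly multichannel).
#' @param stimulus a [speech_envelope] at the model's rate.
#' @param eeg channels x samples matrix or [eeg_recording] matching the
#'   model's channels.
#' @return numeric vector of per-channel correlations.
#' @export
predict_and_score <- function(model, stimulus, eeg) {
  if (inherits(eeg, "eeg_recording")) eeg <- eeg$data
  if (is.null(dim(eeg))) eeg <- matrix(eeg, nrow = 1)
  if (inherits(stimulus, "speech_envelope") &&
      abs(stimulus$rate - model$rate) > 1e-9)
    stop(sprintf("stimulus rate (%g) does not match model rate (%g)",
                 stimulus$rate, model$rate))
  if (nrow(eeg) != nrow(model$weights))
    stop("channel count of `eeg` does not match the model")
  design <- build_lagged_design(stimulus,
                                lag_min = min(model$lag_axis),
                                lag_max = max(model$lag_axis),
                                rate = model$rate)
  n <- nrow(design$matrix)
  valid <- seq.int(max(design$lag_idx, 0) + 1L,
                   n + min(design$lag_idx, 0))
  pred <- design$matrix %*% t(model$weights)  # time x channels
  if (!is.null(model$intercept)) pred <- sweep(pred, 2L, -model$intercept)
  r <- vapply(seq_len(nrow(eeg)), function(ch) {
    p <- pred[valid, ch]; y <- eeg[ch, valid]
    if (stats::sd(p) == 0 || stats::sd(y) == 0) return(NA_real_)
    stats::cor(p, y)
  }, numeric(1))
  if (anyNA(r)) {
    warning("zero-variance prediction or response; returning r = 0")
    r[is.na(r)] <- 0
  }
  r
}

#' Summarize per-electrode CTenv as a top-k mean
#'
#' Cortical lesions (and the volume-conducted fields they distort) make a
#' fixed a-priori electrode selection unreliable in aphasia, so the
#' participant-level CTenv metric averages the `k` electrodes with the
#' highest prediction correlation (default 5).
#'
#' @param per_electrode_r numeric vector of per-channel correlations,
#'   optionally named with channel labels.
#' @param k number of top electrodes to average (`k <=` channel count).
#' @return list of class `ctenv_estimate`: `per_electrode_r`, `top_k_mean`,
#'   `selected_channels`, `k`.
#' @export
ctenv_summary <- function(per_electrode_r, k = 5) {
  if (k > length(per_electrode_r))
    stop(sprintf("k (%d) exceeds channel count (%d)", k,
                 length(per_electrode_r)))
  ord <- order(per_electrode_r, decreasing = TRUE)
  sel <- ord[seq_len(k)]
  labels <- names(per_electrode_r)
  structure(list(
    per_electrode_r = per_electrode_r,
    top_k_mean = mean(per_electrode_r[sel]),
    selected_channels = if (!is.null(labels)) labels[sel] else sel,
    k = k), class = "ctenv_estimate")
}

#' @export
print.ctenv_estimate <- function(x, ...) {
  cat(sprintf("<ctenv_estimate> top-%d mean r = %.4f (channels: %s)\n",
              x$k, x$top_k_mean,
              paste(x$selected_channels, collapse = ", ")))
  invisible(x)
}
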