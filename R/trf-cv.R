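# Leave-one-segment-out cross-validation, lambda selection, and the
# mismatched-pairing permutation null.
#
# All segment-level fits reduce to cached cross-products: with per-segment
# column-centered designs X_s and row-centered responses Y_e, any
# training-set ridge solve needs only sums of X'X and X'Y, and the held-out
# Pearson correlation needs only w'X'y, w'X'Xw and y'y. The permutation
# null therefore reuses one precomputation across all pairings.

# normalize inputs: stimuli -> list of centered design matrices etc.
trf_precompute <- function(stim_segments, eeg_segments,
                           lag_min = -0.1, lag_max = 0.65) {
  if (inherits(eeg_segments, "epoched_eeg")) {
    labels <- eeg_segments$channel_labels
    rate_e <- eeg_segments$rate
    eeg_segments <- eeg_segments$epochs
  } else {
    labels <- rownames(eeg_segments[[1]])
    rate_e <- NULL
  }
  S <- length(stim_segments)
  if (length(eeg_segments) != S)
    stop("stimulus and EEG segment counts differ")
  rate <- if (inherits(stim_segments[[1]], "speech_envelope"))
    stim_segments[[1]]$rate else rate_e
  if (is.null(rate)) stop("cannot determine the sampling rate")
  if (!is.null(rate_e) && abs(rate - rate_e) > 1e-9)
    stop(sprintf("stimulus rate (%g) does not match EEG rate (%g)",
                 rate, rate_e))
  lag_idx <- seq.int(round(lag_min * rate), round(lag_max * rate))
  p <- length(lag_idx)
  Xs <- vector("list", S); XtX <- vector("list", S)
  Ys <- vector("list", S); yty <- vector("list", S)
  valid_list <- vector("list", S)
  for (s in seq_len(S)) {
    x <- if (inherits(stim_segments[[s]], "speech_envelope"))
      stim_segments[[s]]$samples else as.numeric(stim_segments[[s]])
    y <- eeg_segments[[s]]
    if (is.null(dim(y))) y <- matrix(y, nrow = 1)
    if (ncol(y) != length(x))
      stop(sprintf("segment %d: stimulus (%d) and EEG (%d) sample counts differ",
                   s, length(x), ncol(y)))
    X <- lagged_matrix(x, lag_idx)
    n <- nrow(X)
    valid <- seq.int(max(lag_idx, 0) + 1L, n + min(lag_idx, 0))
    X <- X[valid, , drop = FALSE]
    y <- y[, valid, drop = FALSE]
    X <- sweep(X, 2L, colMeans(X), "-")
    y <- y - rowMeans(y)
    Xs[[s]] <- X
    XtX[[s]] <- crossprod(X)
    Ys[[s]] <- t(y)               # time x channels
    yty[[s]] <- colSums(t(y)^2)
    valid_list[[s]] <- valid
  }
  n_ch <- ncol(Ys[[1]])
  list(S = S, p = p, n_ch = n_ch, rate = rate, lag_idx = lag_idx,
       lag_axis = lag_idx / rate, labels = labels,
       X = Xs, XtX = XtX, Y = Ys, yty = yty)
}

# X'_s Y_e for a stimulus segment s and EEG segment e
xty_pair <- function(pre, s, e) crossprod(pre$X[[s]], pre$Y[[e]])

# Leave-one-fold-out CV for a given stimulus-to-EEG pairing.
# pairing[i] = index of the stimulus segment paired with EEG segment i.
# Returns mean CV correlation per lambda, per-electrode r at lambda_best
# (averaged over folds), and lambda_best itself.
cv_pairing <- function(pre, pairing, exponents = 0:20, lambdas = NULL) {
  S <- pre$S
  if (S < 2) stop("leave-one-out cross-validation needs >= 2 segments")
  if (is.null(lambdas)) lambdas <- 2^exponents
  nl <- length(lambdas)
  Xty <- lapply(seq_len(S), function(i) xty_pair(pre, pairing[i], i))
  r_fold <- array(NA_real_, c(S, nl, pre$n_ch))
  for (i in seq_len(S)) {
    train <- setdiff(seq_len(S), i)
    A <- Reduce(`+`, pre$XtX[pairing[train]])
    B <- Reduce(`+`, Xty[train])
    m <- penalty_scale(A)
    eg <- eigen(A, symmetric = TRUE)
    QtB <- crossprod(eg$vectors, B)
    XtX_i <- pre$XtX[[pairing[i]]]
    Xty_i <- Xty[[i]]
    yty_i <- pre$yty[[i]]
    for (l in seq_len(nl)) {
      w <- eg$vectors %*% (QtB / (eg$values + lambdas[l] * m))
      num <- colSums(w * Xty_i)
      pvar <- colSums(w * (XtX_i %*% w))
      denom <- sqrt(pmax(pvar, 0) * yty_i)
      r <- ifelse(denom > 0, num / denom, 0)
      r_fold[i, l, ] <- r
    }
  }
  mean_curve <- apply(r_fold, 2L, mean)
  best <- which.max(mean_curve)
  per_electrode_r <- apply(r_fold[, best, , drop = FALSE], 3L, mean)
  if (!is.null(pre$labels)) names(per_electrode_r) <- pre$labels
  list(lambda_best = lambdas[best],
       per_electrode_r = per_electrode_r,
       cv_curve = data.frame(lambda = lambdas, mean_r = mean_curve),
       r_fold = r_fold)
}

#' Select the ridge parameter by leave-one-segment-out cross-validation
#'
#' For each candidate `lambda = 2^exponent`, TRFs are fitted on all but one
#' segment and used to predict the held-out segment; the `lambda`
#' maximizing the mean held-out correlation (over folds and channels) is
#' selected. Per-electrode correlations at the selected `lambda` are
#' averaged across folds.
#'
#' @param stim_segments list of [speech_envelope] objects (or numeric
#'   vectors), one per segment.
#' @param eeg_segments an [epoched_eeg] or list of channels x samples
#'   matrices, aligned with `stim_segments`.
#' @param exponents integer exponents of the lambda grid (default `0:20`).
#' @param lag_min,lag_max TRF lag window in seconds.
#' @return list: `lambda_best`, `per_electrode_r` (fold-averaged, at
#'   `lambda_best`), `cv_curve` (data.frame lambda/mean_r), `n_folds`.
#' @export
cross_validate_lambda <- function(stim_segments, eeg_segments,
                                  exponents = 0:20,
                                  lag_min = -0.1, lag_max = 0.65) {
  pre <- trf_precompute(stim_segments, eeg_segments, lag_min, lag_max)
  if (pre$S < 2) stop("leave-one-out cross-validation needs >= 2 segments")
  res <- cv_pairing(pre, seq_len(pre$S), exponents = exponents)
  res$r_fold <- NULL
  res$n_folds <- pre$S
  res
}

#' Estimate a participant's TRF and CTenv from segmented data
#'
#' The full estimation path: select `lambda` by leave-one-segment-out
#' cross-validation, refit the TRF on all segments at the selected
#' `lambda`, and summarize the fold-averaged per-electrode correlations as
#' the top-`k` CTenv metric.
#'
#' @inheritParams cross_validate_lambda
#' @param k number of top electrodes averaged into the CTenv scalar.
#' @return list of class `trf_fit`: `model` (multichannel `trf_model`
#'   fitted at `lambda_best` on all segments), `lambda_best`,
#'   `per_electrode_r`, `ctenv` (a `ctenv_estimate`), `cv_curve`.
#' @export
estimate_trf <- function(stim_segments, eeg_segments, exponents = 0:20,
                         lag_min = -0.1, lag_max = 0.65, k = 5) {
  pre <- trf_precompute(stim_segments, eeg_segments, lag_min, lag_max)
  cv <- cv_pairing(pre, seq_len(pre$S), exponents = exponents)
  A <- Reduce(`+`, pre$XtX)
  B <- Reduce(`+`, lapply(seq_len(pre$S), function(i) xty_pair(pre, i, i)))
  w <- solve(A + diag(cv$lambda_best * penalty_scale(A), pre$p), B)
  weights <- t(w)                      # channels x lags
  rownames(weights) <- pre$labels
  model <- structure(list(weights = weights,
                          intercept = rep(0, ncol(w)),
                          lambda = cv$lambda_best, lag_axis = pre$lag_axis,
                          rate = pre$rate),
                     class = "trf_model")
  structure(list(model = model, lambda_best = cv$lambda_best,
                 per_electrode_r = cv$per_electrode_r,
                 ctenv = ctenv_summary(cv$per_electrode_r,
                                       k = min(k, pre$n_ch)),
                 cv_curve = cv$cv_curve),
            class = "trf_fit")
}

#' @export
print.trf_fit <- function(x, ...) {
  cat(sprintf("<trf_fit> lambda = %g; top-%d CTenv = %.4f\n",
              x$lambda_best, x$ctenv$k, x$ctenv$top_k_mean))
  invisible(x)
}

# a uniformly random derangement of 1..n (no fixed points), by rejection
rand_derangement <- function(n) {
  repeat {
    p <- sample.int(n)
    if (!any(p == seq_len(n))) return(p)
  }
}

#' Permutation null distribution of CTenv from mismatched pairings
#'
#' Re-estimates CTenv after deliberately mispairing EEG segments with
#' non-matching stimulus envelopes: each permutation draws a derangement of
#' the segment pairing (no segment keeps its own envelope), reruns the
#' cross-validated estimation path, and records the resulting top-`k` CTenv.
#' Distinct derangements are used when enough exist. By default `lambda` is
#' re-optimized within every permutation (conservative); `refit_lambda =
#' FALSE` scores all permutations at a fixed `lambda` instead.
#'
#' @inheritParams estimate_trf
#' @param n_perm number of permutations (default 100).
#' @param seed integer seed for the permutation draws.
#' @param refit_lambda logical; re-run the lambda search inside each
#'   permutation (default) or score at `lambda` only.
#' @param lambda fixed ridge weight used when `refit_lambda = FALSE`
#'   (defaults to the observed-data `lambda_best`).
#' @return list of class `null_distribution`: `values` (length `n_perm`),
#'   `n_perm`, `seed`, `pairings` (matrix, one row per permutation).
#' @export
null_distribution <- function(stim_segments, eeg_segments, n_perm = 100,
                              seed = 1L, exponents = 0:20,
                              lag_min = -0.1, lag_max = 0.65, k = 5,
                              refit_lambda = TRUE, lambda = NULL) {
  if (n_perm < 1) stop("`n_perm` must be >= 1")
  pre <- trf_precompute(stim_segments, eeg_segments, lag_min, lag_max)
  if (pre$S < 3)
    stop("mismatched permutations need >= 3 segments")
  if (!refit_lambda && is.null(lambda)) {
    obs <- cv_pairing(pre, seq_len(pre$S), exponents = exponents)
    lambda <- obs$lambda_best
  }
  pairings <- with_seed(seed, {
    seen <- character(0)
    out <- matrix(NA_integer_, n_perm, pre$S)
    attempts <- 0L
    i <- 1L
    while (i <= n_perm) {
      d <- rand_derangement(pre$S)
      key <- paste(d, collapse = ",")
      attempts <- attempts + 1L
      if (!(key %in% seen) || attempts > 50L * n_perm) {
        seen <- c(seen, key)
        out[i, ] <- d
        i <- i + 1L
      }
    }
    out
  })
  k_eff <- min(k, pre$n_ch)
  values <- vapply(seq_len(n_perm), function(j) {
    res <- if (refit_lambda)
      cv_pairing(pre, pairings[j, ], exponents = exponents)
    else
      cv_pairing(pre, pairings[j, ], lambdas = lambda)
    ctenv_summary(res$per_electrode_r, k = k_eff)$top_k_mean
  }, numeric(1))
  structure(list(values = values, n_perm = n_perm, seed = seed,
                 pairings = pairings, lambda = lambda,
                 refit_lambda = refit_lambda),
            class = "null_distribution")
}

#' Central interval of a permutation null distribution
#'
#' Computes the central `level` interval of the null CTenv values using
#' type-6 sample quantiles (plotting positions `k/(n+1)`), which are
#' calibrated for the exchangeable comparison "does the observed value fall
#' inside the null's central band": with a finite number of permutations an
#' exchangeable observation falls inside this interval with probability
#' `level`.
#'
#' @param nd a `null_distribution` (or numeric vector of null values).
#' @param level interval mass (default 0.95).
#' @return length-2 numeric: lower and upper bound.
#' @export
null_interval <- function(nd, level = 0.95) {
  v <- if (inherits(nd, "null_distribution")) nd$values else as.numeric(nd)
  a <- (1 - level) / 2
  unname(stats::quantile(v, c(a, 1 - a), type = 6))
}

#' @export
print.null_distribution <- function(x, ...) {
  ci <- null_interval(x)
  cat(sprintf(
    "<null_distribution> %d permutations; mean = %.4f, central 95%% = [%.4f, %.4f]\n",
    x$n_perm, mean(x$values), ci[1], ci[2]))
  invisible(x)
}
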