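test_that("the lagged design has the stated lag count and shift structure", {
  env <- generate_modulated_envelope(10, 128, seed = 1)
  d <- build_lagged_design(env, -0.1, 0.65)
  expect_equal(ncol(d$matrix), 97)
  expect_equal(range(d$lag_idx), c(-13, 83))
  # delaying the stimulus by one sample shifts the columns by one lag
  x <- env$samples
  d0 <- build_lagged_design(x, -0.05, 0.05, rate = 128)
  d1 <- build_lagged_design(c(0, x[-length(x)]), -0.05, 0.05, rate = 128)
  interior <- 100:(length(x) - 100)
  expect_equal(d1$matrix[interior, 1:12], d0$matrix[interior, 2:13])
  # constant stimulus: identical interior columns
  dc <- build_lagged_design(rep(2, 500), -0.05, 0.05, rate = 128)
  expect_true(all(dc$matrix[50:450, ] == 2))
  expect_error(build_lagged_design(x, 0.5, 0.1, rate = 128), "lag_min")
})

test_that("unregularized ridge matches the normal-equation oracle; huge lambda kills weights", {
  set.seed(10)
  x <- rnorm(200)
  d <- build_lagged_design(x, 0, 2 / 128, rate = 128)  # 3 lags
  y <- 0.5 * d$matrix[, 1] - 1.2 * d$matrix[, 2] + 0.3 * d$matrix[, 3] +
    rnorm(200, sd = 0.1) + 2
  m0 <- fit_ridge(d, y, lambda = 0)
  # independent oracle: explicit least squares on the centered system
  Xc <- sweep(d$matrix, 2, colMeans(d$matrix))
  w_oracle <- solve(crossprod(Xc), crossprod(Xc, y - mean(y)))
  expect_lt(max(abs(as.numeric(m0$weights) - as.numeric(w_oracle))), 1e-8)
  m_inf <- fit_ridge(d, y, lambda = 1e12)
  expect_lt(max(abs(m_inf$weights)), 1e-6)
  # singular design at lambda 0
  d2 <- d; d2$matrix[, 3] <- d2$matrix[, 2]
  expect_error(fit_ridge(d2, y, lambda = 0), "lambda > 0")
})

test_that("a planted kernel is recovered exactly from noiseless well-conditioned data", {
  set.seed(11)
  x <- rnorm(4000)
  d <- build_lagged_design(x, -0.05, 0.2, rate = 128)
  w_true <- sin(seq(0, pi, length.out = ncol(d$matrix)))
  y <- as.numeric(d$matrix %*% w_true)
  m <- fit_ridge(d, y, lambda = 0)
  expect_gt(stats::cor(as.numeric(m$weights), w_true), 0.999)
})

test_that("prediction scoring returns signed correlations and guards degenerate input", {
  env <- generate_modulated_envelope(20, 128, seed = 2)
  k <- generate_trf_kernel(standard_montage()[1:3], rate = 128, seed = 2)
  eeg <- synthesize_eeg(env, k, snr_db = Inf)
  model <- structure(list(weights = k$weights, intercept = rep(0, 3),
                          lambda = 0, lag_axis = k$lag_axis, rate = 128),
                     class = "trf_model")
  r <- predict_and_score(model, env, eeg)
  expect_equal(unname(r), rep(1, 3), tolerance = 1e-9)
  r_neg <- predict_and_score(model, env, eeg_recording(-eeg$data, 128,
                                                       eeg$channel_labels))
  expect_equal(unname(r_neg), rep(-1, 3), tolerance = 1e-9)
  # white-noise response uncorrelated with the stimulus stays near zero
  for (s in 1:10) {
    set.seed(s)
    noise <- matrix(rnorm(3 * ncol(eeg$data)), 3)
    rn <- predict_and_score(model, env, noise)
    expect_lt(max(abs(rn)), 3 / sqrt(ncol(eeg$data) - 97))
  }
  flat <- matrix(0, 3, ncol(eeg$data))
  expect_warning(r0 <- predict_and_score(model, env, flat),
                 "zero-variance")
  expect_equal(unname(r0), rep(0, 3))
})

test_that("the top-k CTenv summary equals a sort-then-slice oracle", {
  r <- rep(0.1, 19)
  expect_equal(ctenv_summary(r, 5)$top_k_mean, 0.1)
  set.seed(12)
  for (i in 1:200) {
    v <- rnorm(19)
    names(v) <- standard_montage()
    est <- ctenv_summary(v, 5)
    expect_equal(est$top_k_mean, mean(sort(v, decreasing = TRUE)[1:5]))
    perm <- sample(19)
    expect_equal(ctenv_summary(v[perm], 5)$top_k_mean, est$top_k_mean)
  }
  expect_setequal(ctenv_summary(stats::setNames(1:19 / 20,
                                                standard_montage()),
                                5)$selected_channels,
                  standard_montage()[15:19])
  expect_error(ctenv_summary(rnorm(4), 5), "exceeds")
})
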