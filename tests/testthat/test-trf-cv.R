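test_that("leave-one-segment-out CV uses one fold per segment and reports the curve maximum", {
  p <- make_participant(seed = 1, S = 9, dur = 8, rate = 64, n_ch = 4,
                        snr_db = 0)
  cv <- cross_validate_lambda(p$env_segs, p$eeg_segs)
  expect_equal(cv$n_folds, 9)
  expect_equal(nrow(cv$cv_curve), 21)
  expect_equal(cv$cv_curve$lambda, 2^(0:20))
  best_row <- which.max(cv$cv_curve$mean_r)
  expect_equal(cv$lambda_best, cv$cv_curve$lambda[best_row])
  expect_length(cv$per_electrode_r, 4)
  expect_true(all(abs(cv$per_electrode_r) <= 1))
  expect_error(cross_validate_lambda(p$env_segs[1], p$eeg_segs[1]),
               ">= 2 segments")
})

test_that("noisier data never selects a smaller ridge weight (median over seeds)", {
  pick <- function(seed, snr) {
    p <- make_participant(seed, S = 6, dur = 8, rate = 64, n_ch = 2,
                          snr_db = snr)
    cross_validate_lambda(p$env_segs, p$eeg_segs)$lambda_best
  }
  lo <- vapply(1:7, pick, numeric(1), snr = 10)
  hi <- vapply(1:7, pick, numeric(1), snr = -10)
  expect_gte(stats::median(log2(hi)), stats::median(log2(lo)))
})

test_that("estimate_trf recovers the planted kernel and a high CTenv from clean data", {
  p <- make_participant(seed = 2, S = 9, dur = 10, rate = 64, n_ch = 8,
                        snr_db = Inf)
  fit <- estimate_trf(p$env_segs, p$eeg_segs)
  expect_gt(fit$ctenv$top_k_mean, 0.95)
  expect_gt(stats::cor(as.numeric(fit$model$weights),
                       as.numeric(p$kernel$weights)), 0.95)
  expect_equal(dim(fit$model$weights), dim(p$kernel$weights))
})

test_that("the permutation null uses derangements, the stated length, and a seed", {
  p <- make_participant(seed = 3, S = 5, dur = 6, rate = 64, n_ch = 2,
                        snr_db = 0)
  nd <- null_distribution(p$env_segs, p$eeg_segs, n_perm = 100, seed = 4,
                          refit_lambda = FALSE, lambda = 256)
  expect_length(nd$values, 100)
  expect_false(any(t(nd$pairings) == seq_len(5)))
  nd2 <- null_distribution(p$env_segs, p$eeg_segs, n_perm = 100, seed = 4,
                           refit_lambda = FALSE, lambda = 256)
  expect_identical(nd$values, nd2$values)
  expect_error(null_distribution(p$env_segs, p$eeg_segs, n_perm = 0),
               "n_perm")
  expect_error(null_distribution(p$env_segs[1:2], p$eeg_segs[1:2],
                                 n_perm = 5), ">= 3 segments")
})

test_that("under coupling the observed CTenv exceeds the whole null distribution", {
  p <- make_participant(seed = 5, S = 6, dur = 8, rate = 64, n_ch = 4,
                        snr_db = 10)
  fit <- estimate_trf(p$env_segs, p$eeg_segs)
  nd <- null_distribution(p$env_segs, p$eeg_segs, n_perm = 30, seed = 6,
                          refit_lambda = FALSE, lambda = fit$lambda_best)
  expect_gt(fit$ctenv$top_k_mean, max(nd$values))
  # null mean stays within 2 SE of zero
  se <- stats::sd(nd$values) / sqrt(length(nd$values))
  expect_lt(abs(mean(nd$values)), 2 * se + 0.02)
})
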