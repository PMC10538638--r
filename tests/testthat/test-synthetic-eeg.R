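test_that("ground-truth kernels have biphasic support inside the lag window", {
  k <- generate_trf_kernel(standard_montage(), lag_min = -0.1,
                           lag_max = 0.65, rate = 128, seed = 1)
  expect_equal(nrow(k$weights), 19)
  expect_true(all(diff(k$lag_axis) > 0))
  # nonzero support stays inside the stated window
  nz <- which(colSums(abs(k$weights)) > 1e-10)
  expect_gte(min(k$lag_axis[nz]), -0.1)
  expect_lte(max(k$lag_axis[nz]), 0.65)
  expect_true(all(is.finite(k$weights)))
  # tapered to (near) zero at the window edges
  expect_lt(max(abs(k$weights[, 1])), 1e-10)
  expect_lt(max(abs(k$weights[, ncol(k$weights)])), 1e-10)
  # biphasic: both polarities present
  expect_lt(min(k$weights), 0)
  expect_gt(max(k$weights), 0)
  expect_error(generate_trf_kernel(character(0)), "nonempty")
  expect_error(generate_trf_kernel("Cz", lag_min = 0.5, lag_max = 0.1),
               "lag_min")
})

test_that("synthesized EEG is linear in the kernel and respects SNR extremes", {
  env <- generate_modulated_envelope(20, 128, seed = 3)
  k1 <- generate_trf_kernel(standard_montage()[1:4], rate = 128,
                            amplitude = 1, seed = 3)
  k2 <- k1; k2$weights <- 2 * k1$weights
  e1 <- synthesize_eeg(env, k1, snr_db = Inf)
  e2 <- synthesize_eeg(env, k2, snr_db = Inf)
  expect_equal(e2$data, 2 * e1$data, tolerance = 1e-12)
  # all-zero kernel: output is the noise term alone
  k0 <- k1; k0$weights[] <- 0
  e0 <- synthesize_eeg(env, k0, snr_db = 0, seed = 11)
  noise_only <- synthesize_eeg(env, k0, snr_db = -Inf, seed = 11)
  expect_equal(e0$data, noise_only$data, tolerance = 1e-12)
  expect_false(all(e0$data == 0))
})

test_that("background noise has a 1/f spectrum with the requested exponent", {
  env <- generate_modulated_envelope(120, 128, seed = 4)
  k <- generate_trf_kernel(standard_montage()[1:2], rate = 128, seed = 4)
  noise <- synthesize_eeg(env, k, snr_db = -Inf, noise_exponent = 1,
                          seed = 5)
  x <- noise$data[1, ]
  sp <- stats::spec.pgram(stats::ts(x, frequency = 128), spans = 25,
                          taper = 0.1, plot = FALSE)
  sel <- sp$freq > 0.5 & sp$freq < 30
  slope <- unname(stats::coef(stats::lm(log(sp$spec[sel]) ~
                                          log(sp$freq[sel])))[2])
  expect_lt(abs(slope - (-1)), 0.2)
})

test_that("EEG synthesis is deterministic and validates rates", {
  env <- generate_modulated_envelope(10, 128, seed = 1)
  k <- generate_trf_kernel(standard_montage()[1:3], rate = 128, seed = 1)
  a <- synthesize_eeg(env, k, snr_db = 0, seed = 9)
  b <- synthesize_eeg(env, k, snr_db = 0, seed = 9)
  expect_identical(a$data, b$data)
  k64 <- generate_trf_kernel(standard_montage()[1:3], rate = 64, seed = 1)
  expect_error(synthesize_eeg(env, k64), "128")
  expect_error(synthesize_eeg(env, k64), "64")
})
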