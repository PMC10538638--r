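test_that("the envelope of an AM tone peaks at the modulation rate", {
  fs <- 16000
  tt <- seq_len(10 * fs) / fs
  am <- sin(2 * pi * 1000 * tt) * (1 + 0.8 * sin(2 * pi * 6 * tt)) / 2
  env <- multiband_envelope(am, fs)
  expect_equal(env$rate, 128)
  expect_length(env$samples, 1280)
  expect_lt(abs(modulation_peak(env) - 6), 0.5)
})

test_that("an unmodulated tone yields a flat envelope", {
  fs <- 16000
  tone <- sin(2 * pi * 1000 * seq_len(10 * fs) / fs)
  env <- multiband_envelope(tone, fs)
  expect_lt(stats::sd(env$samples) / mean(env$samples), 0.05)
})

test_that("envelopes of carriers in disjoint bands combine additively", {
  fs <- 16000
  tt <- seq_len(10 * fs) / fs
  c1 <- sin(2 * pi * 300 * tt)
  c2 <- sin(2 * pi * 3000 * tt)
  e1 <- multiband_envelope(c1, fs)$samples
  e2 <- multiband_envelope(c2, fs)$samples
  e12 <- multiband_envelope(c1 + c2, fs)$samples
  expect_lt(max(abs(e12 - (e1 + e2))) / mean(e1 + e2), 0.05)
})

test_that("silent audio warns and returns a zero envelope; scaling is homogeneous", {
  expect_warning(env0 <- multiband_envelope(numeric(16000), 16000),
                 "silent")
  expect_true(all(env0$samples == 0))
  fs <- 16000
  tt <- seq_len(5 * fs) / fs
  am <- sin(2 * pi * 500 * tt) * (1 + 0.5 * sin(2 * pi * 5 * tt)) / 2
  ea <- multiband_envelope(am, fs)$samples
  eb <- multiband_envelope(3 * am, fs)$samples
  expect_equal(eb, 3 * ea, tolerance = 1e-5)
})

test_that("alignment resamples, pads, truncates, and errors on large shortfalls", {
  env <- generate_modulated_envelope(60, 128, seed = 1)
  out <- align_envelope(env, 128, 7680)
  expect_length(out$samples, 7680)
  # round-trip up- and down-sampling stays faithful
  up <- align_envelope(env, 256, 15360)
  back <- align_envelope(up, 128, 7680)
  expect_gt(stats::cor(back$samples, env$samples), 0.999)
  shortfall <- align_envelope(
    speech_envelope(env$samples[1:7670], 128), 128, 7680)
  expect_length(shortfall$samples, 7680)
  expect_equal(attr(shortfall, "alignment")$padded, 10)
  expect_true(all(shortfall$samples[7671:7680] == 0))
  expect_error(align_envelope(speech_envelope(env$samples[1:7000], 128),
                              128, 7680), "shorter")
})
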