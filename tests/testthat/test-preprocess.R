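test_that("downsampling preserves duration and passband, removes content above Nyquist", {
  t5k <- seq_len(10 * 5000) / 5000
  rec <- eeg_recording(matrix(sin(2 * pi * 5 * t5k), 1), 5000, "Cz")
  out <- resample_to(rec, 128)
  expect_equal(ncol(out$data), 1280, tolerance = 1)
  expect_equal(out$rate, 128)
  expect_lt(abs(steady_gain(out$data[1, ], 128, skip_s = 2) - 1), 0.01)
  rec70 <- eeg_recording(matrix(sin(2 * pi * 70 * t5k), 1), 5000, "Cz")
  out70 <- resample_to(rec70, 128)
  expect_lt(steady_gain(out70$data[1, ], 128, skip_s = 2), 0.05)
  expect_error(resample_to(out, 256), "upsampling")
})

test_that("windowed-sinc filtering passes the analysis band and removes drift and DC", {
  r6 <- sinc_filter(sine_recording(6))
  expect_gt(steady_gain(r6$data[1, ], 128), 0.95)
  expect_lt(steady_gain(r6$data[1, ], 128), 1.05)
  r01 <- sinc_filter(sine_recording(0.1))
  expect_lt(steady_gain(r01$data[1, ], 128), 0.1)
  dc <- sinc_filter(eeg_recording(matrix(rep(5, 30 * 128), 1), 128, "Cz"))
  expect_lt(abs(mean(dc$data)), 0.05)
  short <- eeg_recording(matrix(rnorm(100), 1), 128, "Cz")
  expect_error(sinc_filter(short), "order")
})

test_that("mastoid re-referencing zeroes the mastoid mean and keeps scalp differences", {
  set.seed(1)
  labs <- c("Fz", "Cz", "Pz", "M1", "M2")
  rec <- eeg_recording(matrix(rnorm(5 * 256), 5), 128, labs)
  out <- rereference_mastoids(rec)
  m <- colMeans(out$data[4:5, ])
  expect_lt(max(abs(m)), 1e-12)
  expect_equal(out$data[1, ] - out$data[2, ], rec$data[1, ] - rec$data[2, ])
  expect_equal(out$reference, "mastoid-average")
  # invertible from the stored mastoid mean
  restored <- sweep(out$data, 2L, attr(out, "mastoid_mean"), "+")
  expect_equal(restored, rec$data)
  expect_error(rereference_mastoids(out), "already")
  no_m1 <- eeg_recording(rec$data[-4, ], 128, labs[-4])
  expect_error(rereference_mastoids(no_m1), "M1")
})

test_that("epoching cuts one fixed-length epoch per onset and checks bounds", {
  rec <- eeg_recording(matrix(0, 2, 700 * 128), 128, c("Fz", "Cz"))
  onsets <- 10 + (0:8) * 61
  ep <- epoch_segments(rec, onsets, tmin = -5, tmax = 70)
  expect_length(ep, 9)
  expect_equal(ncol(ep$epochs[[1]]), 75 * 128)
  expect_error(epoch_segments(rec, 0, tmin = -5, tmax = 70), "onset 0")
  expect_error(epoch_segments(rec, c(10, 5000)), "5000")
})

test_that("band extraction has the stated Butterworth passbands and guards its input", {
  mk <- function(f) epoched_eeg(
    list(matrix(sin(2 * pi * f * seq_len(30 * 128) / 128), 1)),
    128, "Cz", c(0, 30))
  g <- function(ep) steady_gain(ep$epochs[[1]][1, ], 128)
  expect_gt(g(extract_band(mk(6), "theta")), 0.9)
  expect_lt(g(extract_band(mk(6), "alpha")), 0.25)
  expect_gt(g(extract_band(mk(2), "delta")), 0.9)
  expect_gt(g(extract_band(mk(10), "alpha")), 0.9)
  th <- extract_band(mk(6), "theta")
  expect_equal(th$band, "theta")
  expect_error(extract_band(th, "alpha"), "broadband")
  expect_error(extract_band(mk(6), "gamma"))
})

test_that("artifact rejection zeroes exactly the planted spike windows", {
  set.seed(2)
  clean <- epoched_eeg(list(matrix(rnorm(2 * 10 * 128, sd = 10), 2)),
                       128, c("Fz", "Cz"), c(0, 10))
  out <- reject_artifacts(clean, amplitude_threshold = 500)
  expect_equal(attr(out, "rejection_log")$n_rejected, 0)
  spiked <- clean
  spiked$epochs[[1]][1, 3.5 * 128] <- 600   # inside window 4
  out2 <- reject_artifacts(spiked, amplitude_threshold = 500)
  log2 <- attr(out2, "rejection_log")
  expect_equal(log2$n_rejected, 1)
  expect_equal(log2$rejected_windows[[1]], 4L)
  expect_true(all(out2$epochs[[1]][, (3 * 128 + 1):(4 * 128)] == 0))
  allbad <- clean
  allbad$epochs[[1]][] <- 1000
  expect_error(reject_artifacts(allbad, 500, strict = TRUE), "50%")
})

test_that("evoked averaging finds a planted N1 and flags pure noise", {
  rate <- 128
  set.seed(3)
  n <- 260 * rate
  data <- matrix(rnorm(2 * n, sd = 1), 2)
  bump_t <- seq(0, 0.4, by = 1 / rate)
  bump <- -6 * exp(-0.5 * ((bump_t - 0.1) / 0.02)^2)
  events <- seq(2, 220, by = 2)[1:100]
  for (on in events) {
    idx <- round(on * rate) + seq_along(bump)
    data[, idx] <- data[, idx] + rep(bump, each = 2)
  }
  rec <- eeg_recording(data, rate, c("Fz", "Cz"))
  ev <- evoked_average(rec, events)
  expect_equal(ev$n_trials, 100)
  expect_lt(abs(ev$peaks$latency[1] - 0.1), 0.01)
  expect_true(ev$reliable)
  noise <- eeg_recording(matrix(rnorm(2 * n), 2), rate, c("Fz", "Cz"))
  evn <- evoked_average(noise, events)
  expect_false(evn$reliable)
  expect_error(evoked_average(rec, numeric(0)), "event")
})

test_that("trial averaging shrinks noise roughly as one over root N", {
  rate <- 128
  set.seed(4)
  rec <- eeg_recording(matrix(rnorm(220 * rate), 1), rate, "Cz")
  events <- seq(2, 210, by = 2)
  sd_n <- function(N) {
    ev <- evoked_average(rec, events[seq_len(N)], window = c(-0.2, 0.5))
    stats::sd(ev$waveform[1, ev$times >= 0])
  }
  ratio <- sd_n(4) / sd_n(100)
  expect_gt(ratio, 3)
  expect_lt(ratio, 8)
})
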