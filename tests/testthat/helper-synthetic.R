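# Shared fixture builders; everything is generated in code under fixed seeds.

# a single-channel recording holding a pure sinusoid
sine_recording <- function(freq, rate = 128, duration = 30, amp = 1,
                           labels = "Cz") {
  t <- seq_len(duration * rate) / rate
  eeg_recording(matrix(rep(amp * sin(2 * pi * freq * t),
                           length(labels)),
                       nrow = length(labels), byrow = TRUE),
                rate, labels)
}

# steady-state gain of a filter output against a unit sinusoid input,
# measured away from the edges
steady_gain <- function(data_row, rate, skip_s = 5) {
  idx <- (skip_s * rate):(length(data_row) - skip_s * rate)
  max(abs(data_row[idx]))
}

# matched envelope/EEG segment lists from one synthetic participant
make_participant <- function(seed, S = 9, dur = 10, rate = 64, n_ch = 8,
                             snr_db = 0) {
  env <- generate_modulated_envelope(S * dur, rate, seed = seed)
  kernel <- generate_trf_kernel(standard_montage()[seq_len(n_ch)],
                                rate = rate, seed = seed)
  eeg <- synthesize_eeg(env, kernel, snr_db = snr_db, seed = seed + 10000L)
  n_seg <- dur * rate
  idx <- function(i) ((i - 1L) * n_seg + 1L):(i * n_seg)
  list(
    env_segs = lapply(seq_len(S), function(i)
      speech_envelope(env$samples[idx(i)], rate)),
    eeg_segs = lapply(seq_len(S), function(i)
      eeg$data[, idx(i), drop = FALSE]),
    kernel = kernel, envelope = env, eeg = eeg
  )
}
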