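test_that("cohort tables respect score ranges, size, and determinism", {
  ch <- generate_cohort(seed = 1)
  expect_equal(nrow(ch), 9)
  expect_false(anyDuplicated(ch$id) > 0)
  expect_true(all(ch$severity >= 0 & ch$severity <= 100))
  expect_true(all(ch$rhythm_sync >= 0 & ch$rhythm_sync <= 1))
  expect_identical(ch, generate_cohort(seed = 1))
  expect_false(identical(ch, generate_cohort(seed = 2)))
  expect_error(generate_cohort(2), "at least 3")
})

test_that("zero coupling leaves severity uncorrelated with CTenv at large n", {
  ch <- generate_cohort(5000, beta_delta = 0, beta_theta = 0,
                        beta_alpha = 0, seed = 3)
  for (band in c("ctenv_delta", "ctenv_theta", "ctenv_alpha"))
    expect_lt(abs(stats::cor(ch$severity, ch[[band]])), 0.05)
})

test_that("planted coupling shows up with the right sign", {
  ch <- generate_cohort(2000, beta_delta = -8, beta_theta = 9,
                        beta_alpha = 0, noise_sd = 5, seed = 4)
  expect_gt(stats::cor(ch$severity, ch$ctenv_theta), 0.4)
  expect_lt(stats::cor(ch$severity, ch$ctenv_delta), -0.4)
})

test_that("trial generation yields the full design and validates inputs", {
  ch <- generate_cohort(4, seed = 1)
  tr <- generate_trial_data(ch, seed = 1)
  # 30 items x 5 sessions per participant per condition
  counts <- table(tr$participant, tr$condition)
  expect_true(all(counts == 150))
  expect_true(all(tr$n_correct_words >= 0 & tr$n_correct_words <= tr$n_words))
  expect_true(all(tr$session %in% 1:5))
  expect_identical(tr, generate_trial_data(ch, seed = 1))
  expect_error(generate_trial_data(ch, random_effect_sds = c(
    participant_intercept = -1, participant_session = 0.2,
    item_intercept = 0.5)), "nonnegative")
})

test_that("a positive session effect makes mean accuracy increase over sessions", {
  ch <- generate_cohort(40, seed = 5)
  tr <- generate_trial_data(
    ch, fixed_effects = list(intercept = 0, session = 0.5, ctenv = 0,
                             session_ctenv = 0),
    random_effect_sds = c(participant_intercept = 0,
                          participant_session = 0, item_intercept = 0),
    seed = 5)
  acc <- tapply(tr$n_correct_words / tr$n_words, tr$session, mean)
  expect_true(all(diff(acc) > 0))
})

test_that("a null logistic model centers pooled accuracy at one half", {
  ch <- generate_cohort(30, seed = 6)
  tr <- generate_trial_data(
    ch, fixed_effects = list(intercept = 0, session = 0, ctenv = 0,
                             session_ctenv = 0),
    random_effect_sds = c(participant_intercept = 0,
                          participant_session = 0, item_intercept = 0),
    seed = 6)
  expect_lt(abs(sum(tr$n_correct_words) / sum(tr$n_words) - 0.5), 0.02)
})
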