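test_that("posterior tail fractions count strictly-below-threshold mass", {
  expect_equal(posterior_tail_fraction(c(-2, -1, 1, 2)), 0.5)
  expect_equal(posterior_tail_fraction(rep(-1, 50)), 1)
  expect_equal(posterior_tail_fraction(rep(1, 50)), 0)
  set.seed(1)
  for (i in 1:20) {
    x <- rnorm(500)
    thr <- rnorm(1)
    expect_equal(posterior_tail_fraction(x, thr), sum(x < thr) / 500)
  }
  expect_error(posterior_tail_fraction(numeric(0)), "nonempty")
})

test_that("the robust comparison covers zero for identical groups and detects shifts", {
  covered <- vapply(101:130, function(s) {
    set.seed(s)
    a <- rnorm(25, 0.05, 0.02)
    b <- rnorm(80, 0.05, 0.02)
    rc <- robust_compare(a, b, chains = 2, seed = s)
    d <- rc$summaries[rc$summaries$coefficient == "mean_diff", ]
    expect_lt(d$ci_low, d$ci_high)
    d$ci_low <= 0 && d$ci_high >= 0
  }, logical(1))
  # a 90% interval misses identically-distributed groups ~10% of the time
  expect_gte(mean(covered), 0.75)
  set.seed(2)
  base <- rnorm(40, 0.05, 0.02)
  shifted <- robust_compare(base + 0.1, base, seed = 9)
  d <- shifted$summaries[shifted$summaries$coefficient == "mean_diff", ]
  expect_gt(d$ci_low, 0)
  expect_equal(d$tail_below_zero, 0)
  expect_error(robust_compare(c(1, NA), c(1, 2)), "finite")
  expect_error(robust_compare(1, c(1, 2)), ">= 2")
})

test_that("the Bayesian linear model recovers a strong planted slope", {
  ch <- generate_cohort(200, beta_delta = 0, beta_theta = 9,
                        beta_alpha = 0, noise_sd = 5, seed = 42)
  fit <- fit_bayes_lm(ch$severity,
                      ch[, c("ctenv_delta", "ctenv_theta", "ctenv_alpha")],
                      seed = 1)
  th <- fit$summaries[fit$summaries$coefficient == "ctenv_theta", ]
  expect_lt(abs(th$mean - 9) / 9, 0.1)
  expect_true(th$ci_low <= 9 + 1 && th$ci_high >= 9 - 1)
  # deterministic given the seed
  fit2 <- fit_bayes_lm(ch$severity,
                       ch[, c("ctenv_delta", "ctenv_theta", "ctenv_alpha")],
                       seed = 1)
  expect_identical(fit$summaries, fit2$summaries)
})

test_that("the linear model rejects degenerate inputs by name", {
  ch <- generate_cohort(9, seed = 3)
  bad <- ch[, c("ctenv_delta", "ctenv_theta", "ctenv_alpha")]
  bad$ctenv_theta <- 0.05
  expect_error(fit_bayes_lm(ch$severity, bad), "ctenv_theta")
  expect_error(fit_bayes_lm(ch$severity[1:4], bad[1:4, ]), "n >= ")
})

test_that("the hierarchical logistic model recovers planted fixed effects", {
  fe <- list(intercept = 0.2, session = 0.35, ctenv = 0.9,
             session_ctenv = -0.1)
  ch <- generate_cohort(20, seed = 7)
  tr <- generate_trial_data(ch, fixed_effects = fe, seed = 507)
  fit <- fit_hierarchical_logistic(tr, condition = "rhythm-enhanced",
                                   seed = 7)
  truth <- unlist(fe)
  sm <- fit$summaries
  sd_post <- (sm$ci_high - sm$ci_low) / (2 * stats::qnorm(0.95))
  expect_true(all(abs(sm$mean - truth) < 3 * sd_post))
  expect_equal(sm$coefficient[4], "session_c:ctenv_z")
  # interaction tail fraction is reported and lies in [0, 1]
  expect_true(sm$tail_below_zero[4] >= 0 && sm$tail_below_zero[4] <= 1)
})

test_that("the self-contained MCMC route agrees with the Laplace route", {
  fe <- list(intercept = 0, session = 0.4, ctenv = 0.6, session_ctenv = 0)
  ch <- generate_cohort(8, seed = 8)
  tr <- generate_trial_data(ch, n_items = 10, fixed_effects = fe,
                            seed = 508)
  lap <- fit_hierarchical_logistic(tr, condition = "control", seed = 8)
  mc <- fit_hierarchical_logistic(tr, condition = "control",
                                  method = "mcmc", chains = 2,
                                  warmup = 300, draws = 300, seed = 8)
  sd_lap <- (lap$summaries$ci_high - lap$summaries$ci_low) /
    (2 * stats::qnorm(0.95))
  expect_true(all(abs(mc$summaries$mean - lap$summaries$mean) <
                    pmax(4 * sd_lap, 0.3)))
})

test_that("complete separation and malformed trial tables are rejected", {
  ch <- generate_cohort(4, seed = 9)
  tr <- generate_trial_data(ch, n_items = 5, seed = 9)
  tr$n_correct_words <- tr$n_words
  expect_error(fit_hierarchical_logistic(tr, condition = "control"),
               "separation")
  tr2 <- generate_trial_data(ch, n_items = 5, seed = 9)
  tr2$n_correct_words[1] <- tr2$n_words[1] + 2
  expect_error(fit_hierarchical_logistic(tr2, condition = "control"),
               "n_correct_words")
})
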