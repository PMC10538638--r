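#' Generate a synthetic aphasia cohort with CTenv-coupled scores
#'
#' Emulates a small post-stroke aphasia cohort: per participant, true
#' band-wise cortical-tracking values (delta, theta, alpha) and clinical
#' scores generated as linear functions of those values. Aphasia severity is
#' on the WAB-AQ scale (0-100 aphasia quotient, higher = less impaired),
#' rhythm perception on a beat-alignment-test ability scale, and rhythm
#' synchronization in `[0, 1]`. The coupling coefficients are illustrative
#' defaults (positive theta and negative delta coupling to severity, no
#' alpha coupling) and are expressed per SD of the true CTenv values; they
#' are not estimates of any real effect size.
#'
#' @param n number of participants (>= 3).
#' @param beta_delta,beta_theta,beta_alpha severity change (WAB-AQ points)
#'   per SD of true CTenv in each band.
#' @param noise_sd residual SD of severity (WAB-AQ points).
#' @param intercept mean severity at average CTenv.
#' @param rhythm_betas named list with elements `perception` and `sync`,
#'   each a length-3 numeric (delta, theta, alpha coefficients) on the
#'   respective score scales; defaults are zero coupling.
#' @param seed integer seed.
#' @return data.frame with one row per participant: `id`,
#'   `months_post_onset`, `age`, `severity`, `rhythm_perception`,
#'   `rhythm_sync`, and true values `ctenv_delta`, `ctenv_theta`,
#'   `ctenv_alpha`.
#' @export
generate_cohort <- function(n = 9, beta_delta = -8, beta_theta = 9,
                            beta_alpha = 0, noise_sd = 10, intercept = 45,
                            rhythm_betas = list(perception = c(0, 0, 0),
                                                sync = c(0, 0, 0)),
                            seed = 1L) {
  if (length(n) != 1L || n < 3) stop("`n` must be at least 3")
  n <- as.integer(n)
  with_seed(seed, {
    ctenv <- cbind(
      delta = stats::rnorm(n, 0.06, 0.02),
      theta = stats::rnorm(n, 0.05, 0.02),
      alpha = stats::rnorm(n, 0.03, 0.015)
    )
    z <- scale(ctenv)
    sev <- intercept + z %*% c(beta_delta, beta_theta, beta_alpha) +
      stats::rnorm(n, 0, noise_sd)
    sev <- pmin(pmax(as.numeric(sev), 0), 100)
    rp <- -2.5 + z %*% rhythm_betas$perception + stats::rnorm(n, 0, 1.1)
    rs <- 0.87 + z %*% rhythm_betas$sync + stats::rnorm(n, 0, 0.1)
    rs <- pmin(pmax(as.numeric(rs), 0), 1)
    data.frame(
      id = sprintf("P%02d", seq_len(n)),
      months_post_onset = round(stats::runif(n, 5, 45)),
      age = round(pmin(pmax(stats::rnorm(n, 54, 13), 25), 85)),
      severity = sev,
      rhythm_perception = as.numeric(rp),
      rhythm_sync = rs,
      ctenv_delta = ctenv[, "delta"],
      ctenv_theta = ctenv[, "theta"],
      ctenv_alpha = ctenv[, "alpha"],
      stringsAsFactors = FALSE
    )
  })
}

#' Generate hierarchical trial-level treatment data
#'
#' Simulates a sentence-learning intervention: each participant learns
#' `n_items` scripted sentences over `n_sessions` training sessions under
#' each condition, and the number of correctly produced words per sentence
#' is drawn binomially. On the logit scale,
#' `logit(p) = intercept + session_c * b_sess + ctenv_z * b_ctenv +
#'  session_c * ctenv_z * b_int + u0[participant] + u1[participant] *
#'  session_c + v0[item]`,
#' where `session_c` is the session index centered at the midpoint of
#' treatment (so main effects are interpretable at mid-treatment),
#' `ctenv_z` is the participant's standardized theta-band CTenv, and the
#' random terms are Gaussian with the given SDs.
#'
#' @param cohort a cohort data.frame from [generate_cohort()].
#' @param n_items number of sentences (default 30).
#' @param n_sessions number of training sessions (default 5).
#' @param conditions character vector of condition labels.
#' @param fixed_effects named list: `intercept`, `session`, `ctenv`,
#'   `session_ctenv` (logit scale).
#' @param random_effect_sds named numeric: `participant_intercept`,
#'   `participant_session`, `item_intercept` (all >= 0).
#' @param words_range integer range from which each sentence's word count is
#'   drawn (once per item).
#' @param seed integer seed.
#' @return data.frame with columns `participant`, `item`, `session`,
#'   `condition`, `n_correct_words`, `n_words`, `ctenv_theta`.
#' @export
generate_trial_data <- function(cohort, n_items = 30, n_sessions = 5,
                                conditions = c("rhythm-enhanced", "control"),
                                fixed_effects = list(intercept = 0,
                                                     session = 0.35,
                                                     ctenv = 0.9,
                                                     session_ctenv = -0.1),
                                random_effect_sds = c(
                                  participant_intercept = 0.8,
                                  participant_session = 0.2,
                                  item_intercept = 0.5),
                                words_range = c(4, 9), seed = 1L) {
  if (n_items < 1 || n_sessions < 1)
    stop("`n_items` and `n_sessions` must be >= 1")
  if (any(random_effect_sds < 0))
    stop("random-effect SDs must be nonnegative")
  n_p <- nrow(cohort)
  ctenv_z <- if (n_p > 1 && stats::sd(cohort$ctenv_theta) > 0)
    as.numeric(scale(cohort$ctenv_theta)) else rep(0, n_p)
  with_seed(seed, {
    u0 <- stats::rnorm(n_p, 0, random_effect_sds[["participant_intercept"]])
    u1 <- stats::rnorm(n_p, 0, random_effect_sds[["participant_session"]])
    v0 <- stats::rnorm(n_items, 0, random_effect_sds[["item_intercept"]])
    n_words <- sample(seq(words_range[1], words_range[2]), n_items,
                      replace = TRUE)
    grid <- expand.grid(item = seq_len(n_items), session = seq_len(n_sessions),
                        participant = seq_len(n_p), condition = conditions,
                        KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    s_c <- grid$session - (n_sessions + 1) / 2
    eta <- fixed_effects$intercept +
      s_c * fixed_effects$session +
      ctenv_z[grid$participant] * fixed_effects$ctenv +
      s_c * ctenv_z[grid$participant] * fixed_effects$session_ctenv +
      u0[grid$participant] + u1[grid$participant] * s_c + v0[grid$item]
    p <- stats::plogis(eta)
    nw <- n_words[grid$item]
    data.frame(
      participant = cohort$id[grid$participant],
      item = sprintf("S%02d", grid$item),
      session = grid$session,
      condition = grid$condition,
      n_correct_words = stats::rbinom(nrow(grid), nw, p),
      n_words = nw,
      ctenv_theta = cohort$ctenv_theta[grid$participant],
      stringsAsFactors = FALSE
    )
  })
}
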