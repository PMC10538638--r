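#' Hierarchical logistic model of trial-level treatment response
#'
#' Models trial-level word accuracy (correct words out of words per
#' sentence) as binomial with a logit link. Fixed effects are session
#' (centered at the midpoint of treatment, so main effects are
#' interpretable at mid-treatment), the participant's standardized CTenv,
#' and their interaction; random effects are participant intercepts,
#' participant session slopes, and item intercepts. Models are fitted
#' separately per condition.
#'
#' Two estimation routes are available. `method = "laplace"` (default)
#' obtains the posterior mode and curvature of the fixed effects via the
#' Laplace-approximated marginal likelihood (through [lme4::glmer()]) and
#' draws from the resulting Gaussian approximation. `method = "mcmc"` runs
#' a self-contained blockwise random-walk Metropolis sampler over the joint
#' posterior (fixed effects, all random effects, and log random-effect
#' SDs), with independent Gaussian random-effect distributions and weakly
#' informative priors (`Normal(0, 5)` on fixed effects, half-Cauchy(1) on
#' SDs).
#'
#' @param trials data.frame with columns `participant`, `item`, `session`,
#'   `condition`, `n_correct_words`, `n_words`, and (unless `ctenv` is
#'   given) `ctenv_theta`.
#' @param ctenv optional named numeric vector of per-participant CTenv
#'   values; names must match `trials$participant`.
#' @param condition condition label to model (trials are filtered to it).
#' @param method `"laplace"` or `"mcmc"`.
#' @param chains,warmup,draws posterior sampling settings (per chain).
#' @param seed integer seed.
#' @return list of class `model_fit`: `summaries` for the four fixed
#'   effects (interaction named `session_c:ctenv_z`), `draws`,
#'   `diagnostics`, and (for `"laplace"`) the underlying `glmer` fit.
#' @export
fit_hierarchical_logistic <- function(trials, ctenv = NULL,
                                      condition = "rhythm-enhanced",
                                      method = c("laplace", "mcmc"),
                                      chains = 4, warmup = 500, draws = 500,
                                      seed = 1L) {
  method <- match.arg(method)
  if (any(trials$n_correct_words > trials$n_words) ||
      any(trials$n_correct_words < 0))
    stop("invalid trial counts: need 0 <= n_correct_words <= n_words")
  d <- trials[trials$condition %in% condition, , drop = FALSE]
  if (!nrow(d)) stop(sprintf("no trials for condition '%s'",
                             paste(condition, collapse = "/")))
  if (length(unique(d$participant)) < 2 || length(unique(d$item)) < 2)
    stop("need >= 2 participants and >= 2 items")
  if (all(d$n_correct_words == d$n_words) || all(d$n_correct_words == 0))
    stop(paste("complete separation: every trial is fully correct (or fully",
               "incorrect); the model is not identifiable without stronger",
               "priors"))
  if (is.null(ctenv)) {
    if (!"ctenv_theta" %in% names(d))
      stop("provide `ctenv` or a `ctenv_theta` column in `trials`")
    ctenv <- tapply(d$ctenv_theta, d$participant, mean)
  }
  pid <- as.character(d$participant)
  if (any(!pid %in% names(ctenv)))
    stop("`ctenv` is missing values for some participants")
  cz <- ctenv[unique(pid)]
  cz <- (cz - mean(cz)) / ifelse(stats::sd(cz) > 0, stats::sd(cz), 1)
  d$ctenv_z <- as.numeric(cz[pid])
  d$session_c <- d$session - (min(d$session) + max(d$session)) / 2
  d$participant <- factor(d$participant)
  d$item <- factor(d$item)

  if (method == "laplace") {
    fit <- suppressMessages(lme4::glmer(
      cbind(n_correct_words, n_words - n_correct_words) ~
        session_c * ctenv_z + (1 + session_c | participant) + (1 | item),
      data = d, family = stats::binomial(),
      control = lme4::glmerControl(calc.derivs = FALSE,
                                   check.conv.singular = "ignore")))
    beta <- lme4::fixef(fit)
    V <- as.matrix(stats::vcov(fit))
    post <- with_seed(seed, rmvnorm_chol(chains * draws, beta, V))
    colnames(post) <- names(beta)
    diagnostics <- list(method = "laplace",
                        converged = length(fit@optinfo$conv$lme4) == 0,
                        chains = chains, draws_per_chain = draws)
    extra <- list(glmer_fit = fit)
  } else {
    res <- with_seed(seed, glmm_logit_mcmc(d, chains, warmup, draws))
    post <- res$draws
    diagnostics <- res$diagnostics
    extra <- NULL
  }
  nice <- c("(Intercept)", "session_c", "ctenv_z", "session_c:ctenv_z")
  colnames(post) <- nice[seq_len(ncol(post))]
  summaries <- do.call(rbind, lapply(colnames(post), function(nm)
    summarize_draws(post[, nm], nm)))
  structure(c(list(summaries = summaries, draws = post,
                   diagnostics = diagnostics,
                   data_dims = c(n_trials = nrow(d),
                                 n_participants = nlevels(d$participant),
                                 n_items = nlevels(d$item))),
              extra),
            class = "model_fit")
}

# blockwise random-walk Metropolis for the binomial-logit mixed model;
# exploits that each random effect touches only its own rows
glmm_logit_mcmc <- function(d, chains, warmup, draws) {
  y <- d$n_correct_words; nw <- d$n_words
  Xf <- cbind(1, d$session_c, d$ctenv_z, d$session_c * d$ctenv_z)
  ip <- as.integer(d$participant); ii <- as.integer(d$item)
  np <- max(ip); ni <- max(ii)
  rows_p <- split(seq_along(y), ip); rows_i <- split(seq_along(y), ii)
  ll_rows <- function(eta, r) sum(stats::dbinom(y[r], nw[r],
                                                stats::plogis(eta[r]),
                                                log = TRUE))
  eta_of <- function(beta, u0, u1, v0)
    as.numeric(Xf %*% beta) + u0[ip] + u1[ip] * d$session_c + v0[ii]
  half_cauchy_logsd <- function(ls)  # half-Cauchy(1) on sd, on log scale
    stats::dcauchy(exp(ls), 0, 1, log = TRUE) + ls
  total <- chains * draws
  out <- matrix(NA_real_, total, 4)
  acc_all <- numeric(chains)
  for (ch in seq_len(chains)) {
    beta <- stats::rnorm(4, 0, 0.1)
    u0 <- stats::rnorm(np, 0, 0.1); u1 <- stats::rnorm(np, 0, 0.05)
    v0 <- stats::rnorm(ni, 0, 0.1)
    ls <- log(c(0.5, 0.2, 0.5))  # log SDs: participant int, slope, item int
    eta <- eta_of(beta, u0, u1, v0)
    sc_b <- rep(0.1, 4); sc_u <- 0.3; sc_v <- 0.3; sc_s <- 0.3
    acc <- 0L; tot <- 0L
    for (it in seq_len(warmup + draws)) {
      # fixed effects, componentwise
      for (j in 1:4) {
        prop <- beta; prop[j] <- beta[j] + stats::rnorm(1, 0, sc_b[j])
        eta_new <- eta + (prop[j] - beta[j]) * Xf[, j]
        d_lp <- ll_rows(eta_new, seq_along(y)) - ll_rows(eta, seq_along(y)) +
          stats::dnorm(prop[j], 0, 5, log = TRUE) -
          stats::dnorm(beta[j], 0, 5, log = TRUE)
        if (log(stats::runif(1)) < d_lp) {
          beta <- prop; eta <- eta_new
          if (it <= warmup) sc_b[j] <- sc_b[j] * 1.05
        } else if (it <= warmup) sc_b[j] <- sc_b[j] * 0.97
      }
      # participant effects (intercept and slope jointly per participant)
      for (i in seq_len(np)) {
        r <- rows_p[[i]]
        p0 <- u0[i] + stats::rnorm(1, 0, sc_u)
        p1 <- u1[i] + stats::rnorm(1, 0, sc_u / 2)
        eta_new <- eta
        eta_new[r] <- eta[r] + (p0 - u0[i]) + (p1 - u1[i]) * d$session_c[r]
        d_lp <- ll_rows(eta_new, r) - ll_rows(eta, r) +
          stats::dnorm(p0, 0, exp(ls[1]), log = TRUE) -
          stats::dnorm(u0[i], 0, exp(ls[1]), log = TRUE) +
          stats::dnorm(p1, 0, exp(ls[2]), log = TRUE) -
          stats::dnorm(u1[i], 0, exp(ls[2]), log = TRUE)
        if (log(stats::runif(1)) < d_lp) {
          u0[i] <- p0; u1[i] <- p1; eta <- eta_new
          if (it > warmup) acc <- acc + 1L
        }
        if (it > warmup) tot <- tot + 1L
      }
      # item intercepts
      for (i in seq_len(ni)) {
        r <- rows_i[[i]]
        p0 <- v0[i] + stats::rnorm(1, 0, sc_v)
        eta_new <- eta
        eta_new[r] <- eta[r] + (p0 - v0[i])
        d_lp <- ll_rows(eta_new, r) - ll_rows(eta, r) +
          stats::dnorm(p0, 0, exp(ls[3]), log = TRUE) -
          stats::dnorm(v0[i], 0, exp(ls[3]), log = TRUE)
        if (log(stats::runif(1)) < d_lp) { v0[i] <- p0; eta <- eta_new }
      }
      # random-effect log SDs (prior + random-effect likelihood only)
      re <- list(u0, u1, v0)
      for (j in 1:3) {
        p0 <- ls[j] + stats::rnorm(1, 0, sc_s)
        d_lp <- sum(stats::dnorm(re[[j]], 0, exp(p0), log = TRUE)) -
          sum(stats::dnorm(re[[j]], 0, exp(ls[j]), log = TRUE)) +
          half_cauchy_logsd(p0) - half_cauchy_logsd(ls[j])
        if (log(stats::runif(1)) < d_lp) ls[j] <- p0
      }
      if (it > warmup) out[(ch - 1L) * draws + (it - warmup), ] <- beta
    }
    acc_all[ch] <- if (tot > 0) acc / tot else NA_real_
  }
  list(draws = out,
       diagnostics = list(method = "mcmc", acceptance_rate = acc_all,
                          chains = chains, warmup = warmup,
                          draws_per_chain = draws))
}
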