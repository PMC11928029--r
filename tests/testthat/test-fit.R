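# Likelihoods, BIC, the global optimizer contract, and model comparison.

test_that("an indifferent model scores the coin-flip baseline", {
  cfg <- task_config(p_can_ask = 1)
  s <- run_session(cfg, actor_fixed("Stay", "Safe"), seed = 1)
  # a zero learning rate keeps both stages' values exactly tied, so every
  # one of the 240 free choices has probability 1/2
  ll <- choice_log_likelihood("mf", list(alpha_mf = 0, gamma_mf = 1), s)
  expect_equal(attr(ll, "n"), 240)
  expect_equal(as.numeric(ll), 240 * log(0.5), tolerance = 1e-9)
  expect_equal(round(as.numeric(ll), 3), -166.355)
})

test_that("the model-free likelihood matches a hand-enumerated fixture", {
  s <- two_trial_session()
  alpha <- 0.5; gamma <- 0.5
  # trial 1: both stages tied -> 1/2, 1/2; then Q2[Risky, Cue1] <- 9,
  # Q1[Cue] <- 5.5. trial 2: P(Stay) = 1/(1 + exp(gamma * 5.5));
  # no-cue stage-2 values still tied -> 1/2.
  by_hand <- log(0.5) + log(0.5) + log(1 / (1 + exp(gamma * 5.5))) + log(0.5)
  ll <- choice_log_likelihood("mf", list(alpha_mf = alpha, gamma_mf = gamma), s)
  expect_equal(as.numeric(ll), by_hand, tolerance = 1e-10)
  expect_equal(attr(ll, "n"), 4)
})

test_that("the model-based likelihood matches a hand-enumerated fixture", {
  s <- two_trial_session()
  p <- list(alpha_mb = 0.25, gamma_mb = 1, prior_mb = 6)
  # trial 1: value(Cue) = 5, value(Stay) = 6 -> P(Cue) = 1/(1+e);
  # stage 2 in known Context 1 tied at 6 -> 1/2; risky 12 -> est1 = 7.5.
  # trial 2: marginal 6.75; value(Cue) = .5*7.5 + .5*6 - 1 = 5.75,
  # value(Stay) = 6.75 -> P(Stay) = 1/(1+exp(-1)); stage 2 unknown:
  # values (6, 6.75) -> P(Safe) = 1/(1+exp(0.75)).
  by_hand <- log(1 / (1 + exp(1))) + log(0.5) +
    log(1 / (1 + exp(-1))) + log(1 / (1 + exp(0.75)))
  ll <- choice_log_likelihood("mb", p, s)
  expect_equal(as.numeric(ll), by_hand, tolerance = 1e-10)
})

test_that("the active inference likelihood equals its replayed trace", {
  cfg <- task_config(n_trials = 25)
  params <- list(AL = 0.8, AI = 1.1, EX = 1.5, prior = 0.5, alpha = 0.7)
  tr <- run_agent(params, cfg, seed = 31)
  s <- trace_to_session(tr)
  ll <- choice_log_likelihood("aif", params, s)
  # the trace's stored action probabilities are the likelihood factors
  probs <- c(ifelse(tr$trials$first_action == "Cue", tr$trials$p_cue,
                    1 - tr$trials$p_cue)[tr$trials$can_ask],
             ifelse(tr$trials$second_action == "Risky", tr$trials$p_risky,
                    1 - tr$trials$p_risky))
  expect_equal(as.numeric(ll), sum(log(probs)), tolerance = 1e-9)
  expect_equal(attr(ll, "n"), length(probs))
})

test_that("recorded actions with vanishing probability are floored and flagged", {
  s <- two_trial_session()
  # at this sharpness the recorded Stay on trial 2 has probability
  # exp(-55), far below the log floor
  ll <- choice_log_likelihood("mf", list(alpha_mf = 0.5, gamma_mf = 10), s)
  expect_equal(attr(ll, "n_flagged"), 1L)
  contributions <- c(log(0.5), log(0.5), log(1e-16), log(0.5))
  expect_equal(as.numeric(ll), sum(contributions), tolerance = 1e-9)
})

test_that("generating parameters beat perturbed ones on average", {
  cfg <- task_config(n_trials = 60)
  theta <- list(alpha_mf = 0.3, gamma_mf = 2)
  theta2 <- list(alpha_mf = 0.9, gamma_mf = 0.3)
  d <- vapply(1:8, function(seed) {
    s <- run_rl_agent("mf", theta, cfg, seed = seed)
    as.numeric(choice_log_likelihood("mf", theta, s)) -
      as.numeric(choice_log_likelihood("mf", theta2, s))
  }, numeric(1))
  expect_gt(mean(d), 0)
})

test_that("bic follows its closed form and penalizes parameters", {
  expect_equal(bic(-100, 0, 50), 200)
  expect_equal(bic(-100, 5, 240), 5 * log(240) + 200)
  expect_equal(round(bic(-100, 5, 240), 3), 227.403)
  expect_gt(bic(-100, 3, 240), bic(-100, 2, 240))
  expect_error(bic(-100, -1, 10), "k must")
  expect_error(bic(-100, 2, 0), "n must")
})

test_that("fitting honors the optimizer contract", {
  cfg <- task_config(n_trials = 40)
  s <- run_rl_agent("mf", list(alpha_mf = 0.3, gamma_mf = 2), cfg, seed = 3)
  f <- fit_bandit(s, "mf", budget = c(20, 20), seed = 7)
  # returned score is attained at the returned parameters
  expect_equal(as.numeric(choice_log_likelihood("mf", f$params, s)),
               f$log_likelihood, tolerance = 1e-9)
  # and dominates every probed point
  expect_true(all(f$optimizer_trace$value <= f$log_likelihood + 1e-12))
  expect_equal(nrow(f$optimizer_trace), 40)
  # reproducibility under the seed
  f2 <- fit_bandit(s, "mf", budget = c(20, 20), seed = 7)
  expect_identical(coef(f), coef(f2))
  # BIC identity, also via the logLik method and stats::BIC
  expect_equal(f$bic, f$k * log(f$n) - 2 * f$log_likelihood, tolerance = 1e-9)
  expect_equal(stats::BIC(logLik(f)), f$bic, tolerance = 1e-9)
  expect_error(fit_bandit(s, "mf", budget = c(0, 0)), "invalid budget")
})

test_that("fit methods expose predictions, residuals and simulations", {
  cfg <- task_config(n_trials = 30)
  s <- run_rl_agent("mb", list(alpha_mb = 0.4, gamma_mb = 1.5, prior_mb = 7),
                    cfg, seed = 9)
  f <- fit_bandit(s, "mb", budget = c(25, 25), seed = 2)
  pr <- predict(f)
  expect_equal(nrow(pr), 30)
  expect_true(all(pr$p_obs_second > 0 & pr$p_obs_second <= 1))
  expect_true(all(is.na(pr$p_obs_first[!pr$can_ask])))
  r <- residuals(f)
  expect_equal(length(r), f$n)
  expect_true(all(r >= 0 & r <= 1))
  sims <- simulate(f, nsim = 2, seed = 1)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "bandit_session")
  expect_false(identical(sims[[1]]$reward, sims[[2]]$reward))
})

test_that("model-free parameters are recoverable from their own data", {
  cfg <- task_config()
  est <- vapply(1:10, function(seed) {
    s <- run_rl_agent("mf", list(alpha_mf = 0.3, gamma_mf = 2), cfg,
                      seed = seed)
    coef(fit_bandit(s, "mf", budget = c(60, 60), seed = seed))["alpha_mf"]
  }, numeric(1))
  expect_lt(abs(median(est) - 0.3), 0.2)
})

test_that("model comparison tabulates fits and ignores participant order", {
  cfg <- task_config(n_trials = 25)
  s1 <- run_rl_agent("mf", list(alpha_mf = 0.5, gamma_mf = 1), cfg, seed = 1,
                     participant_id = "p1")
  s2 <- run_rl_agent("mb", list(alpha_mb = 0.5, gamma_mb = 1, prior_mb = 6),
                     cfg, seed = 2, participant_id = "p2")
  cmp <- compare_bandit_models(list(s1, s2), models = c("mf", "mb"),
                               budget = c(10, 10), seed = 5)
  expect_equal(nrow(cmp), 4)
  cmp_rev <- compare_bandit_models(list(s2, s1), models = c("mf", "mb"),
                                   budget = c(10, 10), seed = 5)
  key <- function(x) {
    d <- as.data.frame(x)
    d[order(d$participant, d$model), c("participant", "model", "bic")]
  }
  expect_equal(key(cmp), key(cmp_rev), ignore_attr = TRUE)
  # one participant, three models -> exactly three rows
  cmp3 <- compare_bandit_models(list(s1), budget = c(5, 5), seed = 1)
  expect_equal(nrow(cmp3), 3)
  expect_length(attr(cmp3, "mean_bic"), 3)
})
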