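# Reinforcement learning baselines: delta-rule Q-learning with
# cue-conditioned second-stage values (model-free, k = 2) and a per-context
# mean-estimate planner (model-based, k = 3). Both expose the same
# teacher-forced likelihood interface as the active inference model.

#' Delta-rule value update
#'
#' `q' = q + alpha * (reward - q)`.
#'
#' @param q current value.
#' @param reward received reward.
#' @param alpha_mf learning rate in \[0, 1\].
#' @return updated value.
#' @export
mf_update <- function(q, reward, alpha_mf) {
  if (alpha_mf < 0 || alpha_mf > 1) stop("alpha_mf must lie in [0, 1]")
  q + alpha_mf * (reward - q)
}

#' Softmax choice rule over action values
#'
#' `P(a) = exp(gamma * v_a) / sum(exp(gamma * v))`.
#'
#' @param values numeric vector of action values.
#' @param gamma inverse temperature (>= 0; 0 gives uniform choice).
#' @return probability vector with the names of `values`.
#' @export
softmax_choice <- function(values, gamma) {
  if (gamma < 0) stop("gamma must be >= 0")
  p <- .softmax(gamma * values)
  names(p) <- names(values)
  p
}

#' Update the model-based per-context reward estimates
#'
#' With a known context the matching estimate moves toward the reward by
#' `alpha_mb`. When the context is unknown (`context = NA`) the outcome
#' updates the context-marginal estimate: both per-context estimates move,
#' with learning rates weighted by the marginal context probabilities.
#'
#' @param estimates numeric vector `c(ctx1, ctx2)` of mean-reward
#'   estimates for the risky path.
#' @param context 1, 2 or `NA` (unknown).
#' @param reward received reward.
#' @param alpha_mb learning rate in \[0, 1\].
#' @param p_context1 marginal probability of Context 1.
#' @return updated estimates.
#' @export
mb_update <- function(estimates, context, reward, alpha_mb,
                      p_context1 = 0.5) {
  if (alpha_mb < 0 || alpha_mb > 1) stop("alpha_mb must lie in [0, 1]")
  if (is.na(context)) {
    w <- c(p_context1, 1 - p_context1)
    estimates + alpha_mb * w * (reward - estimates)
  } else {
    estimates[context] <- estimates[context] +
      alpha_mb * (reward - estimates[context])
    estimates
  }
}

#' Model-based planning over both stages
#'
#' Stage-2 value is the better arm's expectation given the (known or
#' marginal) context. Stage-1 value of the cue is the expected best-arm
#' value after the context is revealed, plus the cue cost; the value of
#' staying is the best arm under the marginal estimate. Choice
#' probabilities follow [softmax_choice()].
#'
#' @param estimates numeric vector `c(ctx1, ctx2)` of risky-path estimates.
#' @param params list with `gamma_mb` (and optionally `alpha_mb`,
#'   `prior_mb`).
#' @param config a [task_config()].
#' @param context known context at stage 2 (1, 2) or `NA` for unknown.
#' @return list with `values1`, `stage1` (Stay/Cue probabilities),
#'   `values2`, `stage2` (Safe/Risky probabilities).
#' @export
mb_plan <- function(estimates, params, config, context = NA) {
  safe <- config$safe_reward
  p1 <- config$p_context1
  marginal <- p1 * estimates[1L] + (1 - p1) * estimates[2L]
  v_cue <- p1 * max(safe, estimates[1L]) +
    (1 - p1) * max(safe, estimates[2L]) + config$cue_cost
  v_stay <- max(safe, marginal)
  values1 <- c(Stay = v_stay, Cue = unname(v_cue))
  risky2 <- if (is.na(context)) marginal else estimates[context]
  values2 <- c(Safe = safe, Risky = unname(risky2))
  list(values1 = values1,
       stage1 = softmax_choice(values1, params$gamma_mb),
       values2 = values2,
       stage2 = softmax_choice(values2, params$gamma_mb))
}

# ---- teacher-forced / generative engines ---------------------------------

.mf_params_default <- list(alpha_mf = 0.5, gamma_mf = 1)
.mb_params_default <- list(alpha_mb = 0.5, gamma_mb = 1, prior_mb = 6)

# Model-free engine. Stage-1 values learn the net trial return of Stay vs
# Cue; stage-2 values are conditioned on the revealed information
# (Cue1 / Cue2 / no cue) and initialized at the instructed safe reward.
.mf_engine <- function(params, config, data = NULL, seed = NULL,
                       collect = FALSE) {
  p <- utils::modifyList(.mf_params_default, as.list(params))
  if (p$alpha_mf < 0 || p$alpha_mf > 1) stop("alpha_mf must lie in [0, 1]")
  if (p$gamma_mf < 0) stop("gamma_mf must be >= 0")
  generative <- is.null(data)
  if (generative && !is.null(seed)) set.seed(seed)
  n <- if (generative) config$n_trials else nrow(data)
  q1 <- c(Stay = 0, Cue = 0)
  q2 <- matrix(config$safe_reward, 2, 3,
               dimnames = list(c("Safe", "Risky"), c("Cue1", "Cue2", "Null")))
  ll <- 0; n_free <- 0L; n_flagged <- 0L
  rec <- if (collect) vector("list", n) else NULL
  for (t in seq_len(n)) {
    if (generative) {
      ca <- stats::runif(1) < config$p_can_ask
      ctx <- sample_context(config)
    } else {
      ca <- data$can_ask[t]; ctx <- data$context[t]
    }
    p_stage1 <- softmax_choice(q1, p$gamma_mf)
    if (generative) {
      u1 <- if (!ca) "Stay" else sample(names(p_stage1), 1L, prob = p_stage1)
      o1 <- step_first_choice(ctx, u1, config)$observation
    } else {
      u1 <- data$first_action[t]; o1 <- data$first_observation[t]
    }
    if (ca) {
      n_free <- n_free + 1L
      pa <- p_stage1[[u1]]
      if (pa < .LOG_FLOOR) n_flagged <- n_flagged + 1L
      ll <- ll + log(max(pa, .LOG_FLOOR))
    }
    p_stage2 <- softmax_choice(q2[, o1], p$gamma_mf)
    if (generative) {
      u2 <- sample(names(p_stage2), 1L, prob = p_stage2)
      r <- step_second_choice(ctx, u2, config)
    } else {
      u2 <- data$second_action[t]; r <- data$reward[t]
    }
    n_free <- n_free + 1L
    pa <- p_stage2[[u2]]
    if (pa < .LOG_FLOOR) n_flagged <- n_flagged + 1L
    ll <- ll + log(max(pa, .LOG_FLOOR))
    net <- r + (u1 == "Cue") * config$cue_cost
    q2[u2, o1] <- mf_update(q2[u2, o1], r, p$alpha_mf)
    q1[u1] <- mf_update(q1[u1], net, p$alpha_mf)
    if (collect) {
      rec[[t]] <- data.frame(trial = t, can_ask = ca, context = ctx,
                             first_action = u1, first_observation = o1,
                             second_action = u2, reward = r, net_reward = net,
                             p_cue = p_stage1[["Cue"]],
                             p_risky = p_stage2[["Risky"]],
                             stringsAsFactors = FALSE)
    }
  }
  out <- list(log_likelihood = ll, n = n_free, n_flagged = n_flagged,
              values = list(q1 = q1, q2 = q2))
  if (collect) out$trials <- do.call(rbind, rec)
  out
}

# Model-based engine: per-context mean estimates initialized at prior_mb,
# planning via mb_plan, learning via mb_update (only risky outcomes are
# informative; unknown-context outcomes update the marginal).
.mb_engine <- function(params, config, data = NULL, seed = NULL,
                       collect = FALSE) {
  p <- utils::modifyList(.mb_params_default, as.list(params))
  if (p$alpha_mb < 0 || p$alpha_mb > 1) stop("alpha_mb must lie in [0, 1]")
  if (p$gamma_mb < 0) stop("gamma_mb must be >= 0")
  generative <- is.null(data)
  if (generative && !is.null(seed)) set.seed(seed)
  n <- if (generative) config$n_trials else nrow(data)
  est <- c(p$prior_mb, p$prior_mb)
  ll <- 0; n_free <- 0L; n_flagged <- 0L
  rec <- if (collect) vector("list", n) else NULL
  for (t in seq_len(n)) {
    if (generative) {
      ca <- stats::runif(1) < config$p_can_ask
      ctx <- sample_context(config)
    } else {
      ca <- data$can_ask[t]; ctx <- data$context[t]
    }
    plan1 <- mb_plan(est, p, config, context = NA)
    if (generative) {
      u1 <- if (!ca) "Stay" else sample(names(plan1$stage1), 1L,
                                        prob = plan1$stage1)
      o1 <- step_first_choice(ctx, u1, config)$observation
    } else {
      u1 <- data$first_action[t]; o1 <- data$first_observation[t]
    }
    if (ca) {
      n_free <- n_free + 1L
      pa <- plan1$stage1[[u1]]
      if (pa < .LOG_FLOOR) n_flagged <- n_flagged + 1L
      ll <- ll + log(max(pa, .LOG_FLOOR))
    }
    known <- if (u1 == "Cue") ctx else NA
    plan2 <- mb_plan(est, p, config, context = known)
    if (generative) {
      u2 <- sample(names(plan2$stage2), 1L, prob = plan2$stage2)
      r <- step_second_choice(ctx, u2, config)
    } else {
      u2 <- data$second_action[t]; r <- data$reward[t]
    }
    n_free <- n_free + 1L
    pa <- plan2$stage2[[u2]]
    if (pa < .LOG_FLOOR) n_flagged <- n_flagged + 1L
    ll <- ll + log(max(pa, .LOG_FLOOR))
    if (u2 == "Risky") {
      est <- mb_update(est, known, r, p$alpha_mb, config$p_context1)
    }
    if (collect) {
      rec[[t]] <- data.frame(trial = t, can_ask = ca, context = ctx,
                             first_action = u1, first_observation = o1,
                             second_action = u2, reward = r,
                             net_reward = r + (u1 == "Cue") * config$cue_cost,
                             p_cue = plan1$stage1[["Cue"]],
                             p_risky = plan2$stage2[["Risky"]],
                             stringsAsFactors = FALSE)
    }
  }
  out <- list(log_likelihood = ll, n = n_free, n_flagged = n_flagged,
              values = list(estimates = est))
  if (collect) out$trials <- do.call(rbind, rec)
  out
}

#' Simulate a reinforcement learning agent on the bandit task
#'
#' @param model `"mf"` (delta-rule Q-learning) or `"mb"` (mean-estimate
#'   planner).
#' @param params named parameters: `alpha_mf`, `gamma_mf` for `"mf"`;
#'   `alpha_mb`, `gamma_mb`, `prior_mb` for `"mb"`.
#' @param config a [task_config()].
#' @param seed integer seed.
#' @param participant_id identifier stored with the session.
#' @return a `"bandit_session"`.
#' @export
run_rl_agent <- function(model = c("mf", "mb"), params = list(),
                         config = task_config(), seed = NULL,
                         participant_id = model) {
  model <- match.arg(model)
  eng <- if (model == "mf") {
    .mf_engine(params, config, seed = seed, collect = TRUE)
  } else {
    .mb_engine(params, config, seed = seed, collect = TRUE)
  }
  tr <- eng$trials
  tr <- data.frame(participant_id = participant_id,
                   tr[, c("trial", "can_ask", "context", "first_action",
                          "first_observation", "second_action", "reward",
                          "net_reward")],
                   stringsAsFactors = FALSE)
  as_bandit_session(tr, config)
}
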