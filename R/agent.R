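# The within-trial loop of the active inference agent. A single engine
# serves three purposes: generative simulation (run_agent), teacher-forced
# likelihood evaluation (choice_log_likelihood), and teacher-forced replay
# with full belief traces (compute_regressors, predict).

.aif_params_default <- list(AL = 1, AI = 1, EX = 1, prior = 0.25, alpha = 1,
                            gamma = 4)

.aif_build_model <- function(params, config) {
  p <- utils::modifyList(.aif_params_default, as.list(params))
  scale <- if (is.null(p$preference_scale)) 0.25 else p$preference_scale
  aif_model(prior = p$prior, AL = p$AL, AI = p$AI, EX = p$EX,
            alpha = p$alpha, gamma = p$gamma, config = config,
            preference_scale = scale)
}

# data = NULL: generative mode (environment sampled, actions sampled from
# the action marginals). data = bandit_session: realized observations and
# actions are replayed; free choices accumulate the log likelihood.
.aif_engine <- function(params, config, data = NULL, seed = NULL,
                        collect = FALSE, participant_id = "agent") {
  model <- .aif_build_model(params, config)
  pars <- model$pars
  generative <- is.null(data)
  if (generative && !is.null(seed)) set.seed(seed)
  n <- if (generative) config$n_trials else nrow(data)
  rv <- config$reward_values
  i_rewards <- model$idx$rewards
  obs_value <- numeric(length(model$observations))
  obs_value[i_rewards] <- rv
  obs_value[model$idx$cue] <- 0
  d <- model$d
  B <- model$B
  ll <- 0; n_free <- 0L; n_flagged <- 0L

  if (collect) {
    trials <- data.frame(
      trial = seq_len(n), can_ask = NA, context = NA_integer_,
      first_action = NA_character_, first_observation = NA_character_,
      second_action = NA_character_, reward = NA_real_, net_reward = NA_real_,
      p_cue = NA_real_, p_risky = NA_real_, pe = NA_real_, pe_abs = NA_real_,
      expected_risky_ctx1 = NA_real_, expected_risky_ctx2 = NA_real_,
      policy_entropy = NA_real_, stringsAsFactors = FALSE)
    q_policy <- matrix(NA_real_, n, 4,
                       dimnames = list(NULL, rownames(model$policies)))
    efe <- lapply(c("G", "novelty_value", "variability_value",
                    "extrinsic_value", "raw_novelty", "raw_salience"),
                  function(nm) q_policy)
    names(efe) <- c("G", "novelty_value", "variability_value",
                    "extrinsic_value", "raw_novelty", "raw_salience")
    chosen_cols <- c("G", "novelty_value", "variability_value",
                     "extrinsic_value", "raw_novelty", "raw_salience")
    stage1_chosen <- matrix(NA_real_, n, 6, dimnames = list(NULL, chosen_cols))
    stage2_chosen <- stage1_chosen
    realized <- data.frame(state_info_gain = rep(NA_real_, n),
                           novelty_reduction = NA_real_)
  }

  for (t in seq_len(n)) {
    if (generative) {
      ca <- stats::runif(1) < config$p_can_ask
      ctx <- sample_context(config)
    } else {
      ca <- data$can_ask[t]
      ctx <- data$context[t]
    }
    pre <- .aif_precompute(model)
    s1 <- NULL; qpi <- NULL; marg1 <- NULL
    if (ca || collect) {
      s1 <- .stage1_policy_terms(d, pre, model)
      qpi <- policy_posterior(s1$G, pars$gamma)
      marg1 <- action_marginal(qpi, "first")
    }
    if (generative) {
      u1 <- if (!ca) "Stay" else {
        sample(c("Stay", "Cue"), 1L, prob = marg1)
      }
      first <- step_first_choice(ctx, u1, config)
      o1_lab <- first$observation
    } else {
      u1 <- data$first_action[t]
      o1_lab <- data$first_observation[t]
    }
    if (ca) {
      n_free <- n_free + 1L
      p1 <- marg1[[u1]]
      if (p1 < .LOG_FLOOR) n_flagged <- n_flagged + 1L
      ll <- ll + log(max(p1, .LOG_FLOOR))
    }
    o1 <- match(o1_lab, model$observations)
    if (is.na(o1) && o1_lab == "Null") o1 <- model$idx$null
    qpred1 <- drop(B[[u1]] %*% d)
    post1 <- pre$A[o1, ] * qpred1
    s <- sum(post1)
    if (s < 1e-14) stop("impossible observation under every hidden state")
    q1 <- post1 / s

    s2 <- .stage2_policy_terms(q1, pre, model)
    q2pi <- .softmax(-pars$gamma * s2$G)
    if (generative) {
      u2 <- sample(c("Safe", "Risky"), 1L, prob = q2pi)
      r <- step_second_choice(ctx, u2, config)
    } else {
      u2 <- data$second_action[t]
      r <- data$reward[t]
    }
    i2 <- match(u2, s2$names)
    n_free <- n_free + 1L
    p2 <- q2pi[i2]
    if (p2 < .LOG_FLOOR) n_flagged <- n_flagged + 1L
    ll <- ll + log(max(p2, .LOG_FLOOR))

    qpred2 <- drop(B[[u2]] %*% q1)
    exp_reward <- sum(obs_value * drop(pre$A %*% qpred2))
    pe <- r - exp_reward
    o2 <- i_rewards[match(r, rv)]
    if (is.na(o2)) stop("reward not in the configured reward values: ", r)
    post2 <- pre$A[o2, ] * qpred2
    s <- sum(post2)
    if (s < 1e-14) stop("impossible observation under every hidden state")
    q2 <- post2 / s
    a_new <- model$a
    a_new[o2, ] <- a_new[o2, ] + pars$alpha * q2

    if (collect) {
      w1 <- if (u1 == "Cue") qpi[1:2] else qpi[3:4]
      w1 <- w1 / sum(w1)
      sel <- if (u1 == "Cue") 1:2 else 3:4
      for (nm in names(efe)) efe[[nm]][t, ] <- s1[[nm]]
      stage1_chosen[t, ] <- vapply(chosen_cols, function(nm) {
        sum(w1 * s1[[nm]][sel])
      }, numeric(1))
      stage2_chosen[t, ] <- vapply(chosen_cols, function(nm) {
        s2[[nm]][i2]
      }, numeric(1))
      q_policy[t, ] <- qpi
      nz <- q1 > 0 & qpred1 > 0
      realized$state_info_gain[t] <- sum(q1[nz] * (log(q1[nz]) - log(qpred1[nz])))
      realized$novelty_reduction[t] <- -.dirichlet_kl_matrix(a_new, model$a)
      cs7 <- sum(a_new[, 7]); cs8 <- sum(a_new[, 8])
      trials$can_ask[t] <- ca
      trials$context[t] <- ctx
      trials$first_action[t] <- u1
      trials$first_observation[t] <- o1_lab
      trials$second_action[t] <- u2
      trials$reward[t] <- r
      trials$net_reward[t] <- r + (u1 == "Cue") * config$cue_cost
      trials$p_cue[t] <- marg1[["Cue"]]
      trials$p_risky[t] <- q2pi[2L]
      trials$pe[t] <- pe
      trials$pe_abs[t] <- abs(pe)
      trials$expected_risky_ctx1[t] <-
        sum(rv * a_new[i_rewards, 7]) / cs7
      trials$expected_risky_ctx2[t] <-
        sum(rv * a_new[i_rewards, 8]) / cs8
      trials$policy_entropy[t] <- -sum(qpi * .safe_log(qpi))
    }
    model$a <- a_new
  }

  out <- list(log_likelihood = ll, n = n_free, n_flagged = n_flagged,
              model = model)
  if (collect) {
    out$trials <- trials
    out$q_policy <- q_policy
    out$efe <- efe
    out$stage1_chosen <- as.data.frame(stage1_chosen)
    out$stage2_chosen <- as.data.frame(stage2_chosen)
    out$realized <- realized
  }
  out
}

#' Simulate an active inference agent on the bandit task
#'
#' Runs a full session: per trial the state belief is reset to the prior
#' `d` (the context is redrawn every trial), the expected free energy of
#' all four policies is evaluated, the first action is sampled from the
#' policy-posterior action marginal (forced to Stay on no-ask trials), the
#' belief is updated with the first result, the remaining policies are
#' re-evaluated for the second choice, and after the reward the likelihood
#' concentrations are updated with the learning rate `alpha`.
#'
#' @param params named list (or vector) of model parameters: any of `AL`,
#'   `AI`, `EX`, `prior`, `alpha`, `gamma` (unsupplied entries take the
#'   [aif_model()] defaults).
#' @param config a [task_config()].
#' @param seed integer seed; identical seeds give identical traces.
#' @param participant_id identifier stored with the trace.
#' @return an object of class `"aif_trace"`: a list with `trials` (per-trial
#'   records, action probabilities, prediction errors, risky-reward
#'   estimates, policy entropy), `q_policy` (trials x 4 policy posterior),
#'   `efe` (per-policy decomposition matrices), chosen-action
#'   decompositions per stage, realized belief-update quantities, and the
#'   final model.
#' @examples
#' tr <- run_agent(list(AL = 1, AI = 1, EX = 1), task_config(n_trials = 20),
#'                 seed = 1)
#' head(tr$trials[, c("first_action", "second_action", "reward")])
#' @export
run_agent <- function(params = list(), config = task_config(), seed = NULL,
                      participant_id = "agent") {
  eng <- .aif_engine(params, config, data = NULL, seed = seed,
                     collect = TRUE, participant_id = participant_id)
  structure(
    list(trials = eng$trials, q_policy = eng$q_policy, efe = eng$efe,
         stage1_chosen = eng$stage1_chosen, stage2_chosen = eng$stage2_chosen,
         realized = eng$realized, params = eng$model$pars, config = config,
         model = eng$model, participant_id = participant_id, seed = seed),
    class = "aif_trace"
  )
}

#' @export
print.aif_trace <- function(x, ...) {
  tr <- x$trials
  cat(sprintf("Active inference trace: %d trials (seed %s)\n", nrow(tr),
              if (is.null(x$seed)) "unset" else x$seed))
  free <- tr$can_ask
  cat(sprintf("  Cue frequency on can-ask trials: %.2f\n",
              mean(tr$first_action[free] == "Cue")))
  cat(sprintf("  mean |prediction error|: %.2f apples\n", mean(tr$pe_abs)))
  cat(sprintf("  final risky estimates: Context 1 %.2f, Context 2 %.2f\n",
              tr$expected_risky_ctx1[nrow(tr)],
              tr$expected_risky_ctx2[nrow(tr)]))
  invisible(x)
}

#' @export
plot.aif_trace <- function(x, ...) {
  tr <- x$trials
  op <- graphics::par(mfrow = c(4, 1), mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(op))
  graphics::plot(tr$trial, tr$p_cue, type = "l", ylim = c(0, 1),
                 xlab = "", ylab = "P(Cue)", main = "First choice")
  graphics::points(tr$trial, as.numeric(tr$first_action == "Cue"),
                   pch = 3, col = ifelse(tr$can_ask, "darkgreen", "grey"))
  graphics::plot(tr$trial, tr$p_risky, type = "l", ylim = c(0, 1),
                 xlab = "", ylab = "P(Risky)", main = "Second choice")
  graphics::points(tr$trial, as.numeric(tr$second_action == "Risky"),
                   pch = 3, col = c("orange", "blue")[tr$context])
  graphics::plot(tr$trial, tr$pe_abs, type = "h", xlab = "",
                 ylab = "|PE| (apples)", main = "Prediction error")
  graphics::matplot(tr$trial,
                    cbind(tr$expected_risky_ctx1, tr$expected_risky_ctx2),
                    type = "l", lty = 1, col = c("blue", "orange"),
                    xlab = "trial", ylab = "E[risky reward]",
                    main = "Risky-path reward estimates")
  graphics::legend("right", legend = c("Context 1", "Context 2"),
                   col = c("blue", "orange"), lty = 1, bty = "n")
  invisible(x)
}

#' Reward prediction error under the agent's beliefs
#'
#' Discrepancy between a received reward and the reward the agent expected
#' from the chosen second-stage action, where the expectation combines the
#' likelihood beliefs `A` with the current context belief.
#'
#' @param reward received reward in apples.
#' @param model an [aif_model()].
#' @param chosen_action `"Safe"` or `"Risky"`.
#' @param context_belief probability vector (length 2) over contexts.
#' @param type `"absolute"` (default) or `"signed"`.
#' @return prediction error in apples.
#' @export
prediction_error <- function(reward, model, chosen_action, context_belief,
                             type = c("absolute", "signed")) {
  type <- match.arg(type)
  .check_action(chosen_action, c("Safe", "Risky"))
  if (!.is_prob_vector(context_belief) || length(context_belief) != 2L) {
    stop("context_belief must be a probability vector over the 2 contexts")
  }
  expected <- if (chosen_action == "Safe") {
    A <- normalize_likelihood(model$a)
    cols <- A[, model$idx$s_safe]
    sum(model$config$reward_values *
          (cols[model$idx$rewards, ] %*% context_belief))
  } else {
    context_belief[1L] * expected_risky_reward(model, 1L) +
      context_belief[2L] * expected_risky_reward(model, 2L)
  }
  pe <- reward - expected
  if (type == "absolute") abs(pe) else pe
}

#' Block summaries of action frequencies
#'
#' Splits a trace or session into consecutive blocks of trials and reports
#' the frequency of consulting the cue (among can-ask trials) and of
#' choosing the risky path, split by the information revealed at the first
#' result (Cue1, Cue2, or no cue).
#'
#' @param trace an `"aif_trace"` or `"bandit_session"` (any data frame with
#'   the session columns works).
#' @param block block length in trials; a shorter tail block is kept.
#' @return data frame with one row per block.
#' @export
summarize_policy_blocks <- function(trace, block = 20L) {
  tr <- if (inherits(trace, "aif_trace")) trace$trials else as.data.frame(trace)
  if (block < 1L) stop("block must be >= 1")
  idx <- ceiling(seq_len(nrow(tr)) / block)
  one <- function(rows) {
    b <- tr[rows, ]
    ask <- b$can_ask
    data.frame(
      first_trial = min(b$trial), last_trial = max(b$trial),
      n_can_ask = sum(ask),
      cue_freq = if (any(ask)) mean(b$first_action[ask] == "Cue") else NA_real_,
      risky_given_cue1 = .freq_risky(b, "Cue1"),
      risky_given_cue2 = .freq_risky(b, "Cue2"),
      risky_given_nocue = .freq_risky(b, "Null")
    )
  }
  out <- do.call(rbind, lapply(split(seq_len(nrow(tr)), idx), one))
  rownames(out) <- NULL
  cbind(block = sort(unique(idx)), out)
}

.freq_risky <- function(b, obs) {
  sel <- b$first_observation == obs
  if (!any(sel)) return(NA_real_)
  mean(b$second_action[sel] == "Risky")
}

# Extract a plain bandit_session from a generative trace.
#' Convert a simulated trace to a behavioral session
#'
#' @param trace an `"aif_trace"` from [run_agent()].
#' @return a `"bandit_session"` with the standard columns.
#' @export
trace_to_session <- function(trace) {
  tr <- trace$trials
  as_bandit_session(
    data.frame(participant_id = trace$participant_id, trial = tr$trial,
               can_ask = tr$can_ask, context = tr$context,
               first_action = tr$first_action,
               first_observation = tr$first_observation,
               second_action = tr$second_action, reward = tr$reward,
               net_reward = tr$net_reward, stringsAsFactors = FALSE),
    trace$config
  )
}
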