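#' Configuration of the contextual two-armed bandit task
#'
#' Defines the true generative process of the task: a safe path paying a
#' fixed reward, a risky path whose reward distribution depends on a hidden
#' context that is redrawn every trial, and a purchasable cue that reveals
#' the context at a cost. Defaults reproduce the administered task: rewards
#' of 0/3/6/9/12 apples, Context 1 paying
#' (5\%, 5\%, 10\%, 25\%, 55\%) over those values (mean 9.6) and Context 2
#' the reverse (mean 2.4), a +6 safe path, a -1 cue, 120 trials, and a
#' starting endowment of 5 apples.
#'
#' @param n_trials number of trials per session (default 120).
#' @param reward_values strictly increasing vector of possible risky rewards,
#'   in apples.
#' @param ctx1_probs,ctx2_probs probability vectors over `reward_values` for
#'   the two contexts; each must sum to 1.
#' @param safe_reward fixed payoff of the safe path; must be one of
#'   `reward_values`.
#' @param cue_cost payoff (negative) of consulting the cue.
#' @param initial_reward starting endowment, in apples.
#' @param p_context1 per-trial probability that the risky path is in
#'   Context 1.
#' @param p_can_ask per-trial probability that the cue is available
#'   ("you can ask" trials).
#' @param seed optional integer seed stored with the configuration and used
#'   as the default by [run_session()].
#' @return an object of class `"task_config"`.
#' @examples
#' cfg <- task_config()
#' cfg
#' @export
task_config <- function(n_trials = 120L,
                        reward_values = c(0, 3, 6, 9, 12),
                        ctx1_probs = c(0.05, 0.05, 0.10, 0.25, 0.55),
                        ctx2_probs = c(0.55, 0.25, 0.10, 0.05, 0.05),
                        safe_reward = 6,
                        cue_cost = -1,
                        initial_reward = 5,
                        p_context1 = 0.5,
                        p_can_ask = 0.5,
                        seed = NULL) {
  n_trials <- as.integer(n_trials)
  if (is.na(n_trials) || n_trials < 1L) stop("n_trials must be >= 1")
  if (length(ctx1_probs) != length(reward_values) ||
      length(ctx2_probs) != length(reward_values)) {
    stop("context probability vectors must match reward_values in length")
  }
  if (any(diff(reward_values) <= 0)) {
    stop("reward_values must be strictly increasing")
  }
  for (p in list(ctx1_probs, ctx2_probs)) {
    if (any(p < 0) || any(p > 1)) stop("probabilities must lie in [0, 1]")
    if (abs(sum(p) - 1) > 1e-12) stop("context probabilities must sum to 1")
  }
  for (p in c(p_context1, p_can_ask)) {
    if (p < 0 || p > 1) stop("probabilities must lie in [0, 1]")
  }
  if (!safe_reward %in% reward_values) {
    stop("safe_reward must be one of reward_values")
  }
  structure(
    list(n_trials = n_trials, reward_values = reward_values,
         ctx1_probs = ctx1_probs, ctx2_probs = ctx2_probs,
         safe_reward = safe_reward, cue_cost = cue_cost,
         initial_reward = initial_reward, p_context1 = p_context1,
         p_can_ask = p_can_ask, seed = seed),
    class = "task_config"
  )
}

#' @export
print.task_config <- function(x, ...) {
  cat("Contextual two-armed bandit task\n")
  cat(sprintf("  trials: %d   safe: %+g   cue: %+g   start: %g apples\n",
              x$n_trials, x$safe_reward, x$cue_cost, x$initial_reward))
  cat("  risky rewards:", paste(x$reward_values, collapse = " "), "\n")
  cat("  Context 1 probs:", paste(format(x$ctx1_probs), collapse = " "),
      sprintf(" (mean %.1f)\n", sum(x$ctx1_probs * x$reward_values)))
  cat("  Context 2 probs:", paste(format(x$ctx2_probs), collapse = " "),
      sprintf(" (mean %.1f)\n", sum(x$ctx2_probs * x$reward_values)))
  cat(sprintf("  P(Context 1) = %g,  P(can ask) = %g\n",
              x$p_context1, x$p_can_ask))
  invisible(x)
}

.check_action <- function(action, allowed) {
  if (!(is.character(action) && length(action) == 1L && action %in% allowed)) {
    stop(sprintf("invalid action: expected one of %s",
                 paste(allowed, collapse = ", ")))
  }
  action
}

#' Sample the hidden context of one or more trials
#'
#' @param config a [task_config()].
#' @param n number of independent draws.
#' @return integer vector of 1 (Context 1) and 2 (Context 2).
#' @export
sample_context <- function(config, n = 1L) {
  ifelse(stats::runif(n) < config$p_context1, 1L, 2L)
}

#' First-stage transition: stay or consult the cue
#'
#' The "Stay" option gives nothing and no information; the "Cue" option
#' costs `cue_cost` and reveals the trial's context.
#'
#' @param context integer context (1 or 2).
#' @param action `"Stay"` or `"Cue"`.
#' @param config a [task_config()].
#' @return list with `observation` (`"Null"`, `"Cue1"` or `"Cue2"`) and
#'   `reward` in apples.
#' @export
step_first_choice <- function(context, action, config) {
  .check_action(action, c("Stay", "Cue"))
  if (action == "Stay") {
    list(observation = "Null", reward = 0)
  } else {
    list(observation = paste0("Cue", context), reward = config$cue_cost)
  }
}

#' Second-stage transition: safe or risky path
#'
#' @param context integer context (1 or 2); determines the risky reward
#'   distribution.
#' @param action `"Safe"` or `"Risky"`.
#' @param config a [task_config()].
#' @return reward in apples.
#' @export
step_second_choice <- function(context, action, config) {
  .check_action(action, c("Safe", "Risky"))
  if (action == "Safe") return(config$safe_reward)
  probs <- if (context == 1L) config$ctx1_probs else config$ctx2_probs
  config$reward_values[sample.int(length(probs), 1L, prob = probs)]
}

#' Bernoulli schedule of "you can ask" trials
#'
#' @param config a [task_config()].
#' @param n number of trials (defaults to `config$n_trials`).
#' @return logical vector; `FALSE` marks forced-Stay trials.
#' @export
can_ask_schedule <- function(config, n = config$n_trials) {
  stats::runif(n) < config$p_can_ask
}

#' Fixed-action actor for [run_session()]
#'
#' @param first,second action labels returned at the two stages.
#' @return an actor function.
#' @export
actor_fixed <- function(first = "Stay", second = "Safe") {
  function(stage, trial, can_ask, observation) {
    if (stage == "first") first else second
  }
}

#' Simulate a full session of the task
#'
#' Runs `n_trials` trials of the bandit, querying `actor` for a first-stage
#' action on can-ask trials (forced to `"Stay"` otherwise) and for a
#' second-stage action after the first result is revealed.
#'
#' @param config a [task_config()].
#' @param actor a function `(stage, trial, can_ask, observation)` returning
#'   `"Stay"`/`"Cue"` when `stage == "first"` and `"Safe"`/`"Risky"` when
#'   `stage == "second"`; `observation` is the first-stage outcome label.
#' @param seed optional integer seed; the same seed and actor give a
#'   byte-identical session.
#' @param participant_id identifier stored with the session.
#' @return a `"bandit_session"` data frame with one row per trial and
#'   attributes `cumulative_reward` and `config`.
#' @examples
#' s <- run_session(task_config(), actor_fixed("Stay", "Safe"), seed = 1)
#' attr(s, "cumulative_reward")  # 5 + 120 * 6
#' @export
run_session <- function(config, actor, seed = config$seed,
                        participant_id = "sim") {
  if (!is.null(seed)) set.seed(seed)
  n <- config$n_trials
  can_ask <- logical(n); context <- integer(n)
  a1 <- character(n); o1 <- character(n); a2 <- character(n)
  reward <- numeric(n); net <- numeric(n)
  for (t in seq_len(n)) {
    can_ask[t] <- stats::runif(1) < config$p_can_ask
    context[t] <- sample_context(config)
    a1[t] <- if (!can_ask[t]) "Stay" else {
      .check_action(actor("first", t, can_ask[t], NULL), c("Stay", "Cue"))
    }
    first <- step_first_choice(context[t], a1[t], config)
    o1[t] <- first$observation
    a2[t] <- .check_action(actor("second", t, can_ask[t], o1[t]),
                           c("Safe", "Risky"))
    reward[t] <- step_second_choice(context[t], a2[t], config)
    net[t] <- reward[t] + first$reward
  }
  as_bandit_session(
    data.frame(participant_id = participant_id, trial = seq_len(n),
               can_ask = can_ask, context = context, first_action = a1,
               first_observation = o1, second_action = a2, reward = reward,
               net_reward = net, stringsAsFactors = FALSE),
    config
  )
}

#' Mark a data frame of trial records as a bandit session
#'
#' Validates the within-trial consistency rules (forced trials are Stay,
#' Stay yields no cue, the cue matches the context, Safe pays the safe
#' reward, and net reward accounts for the cue cost) and attaches the
#' cumulative reward.
#'
#' @param df data frame with the session columns (see [run_session()]).
#' @param config the [task_config()] the records were generated under.
#' @return a `"bandit_session"` object.
#' @export
as_bandit_session <- function(df, config = task_config()) {
  needed <- c("participant_id", "trial", "can_ask", "context", "first_action",
              "first_observation", "second_action", "reward", "net_reward")
  if (!all(needed %in% names(df))) stop("missing session columns")
  with(df, {
    if (any(!can_ask & first_action != "Stay")) {
      stop("forced trials must record first_action == 'Stay'")
    }
    if (any(first_action == "Stay" & first_observation != "Null")) {
      stop("Stay must yield the Null observation")
    }
    cue <- first_action == "Cue"
    if (any(cue & first_observation != paste0("Cue", context))) {
      stop("cue observation must match the context")
    }
    if (any(second_action == "Safe" & reward != config$safe_reward)) {
      stop("Safe must pay the safe reward")
    }
    if (any(abs(net_reward - (reward + cue * config$cue_cost)) > 1e-12)) {
      stop("net_reward must equal reward plus the cue cost when asked")
    }
  })
  structure(df,
            class = c("bandit_session", "data.frame"),
            cumulative_reward = config$initial_reward + sum(df$net_reward),
            config = config)
}

#' @export
print.bandit_session <- function(x, ...) {
  cat(sprintf("Bandit session '%s': %d trials, cumulative reward %g apples\n",
              x$participant_id[1], nrow(x), attr(x, "cumulative_reward")))
  print.data.frame(utils::head(as.data.frame(x), 5))
  if (nrow(x) > 5) cat("...", nrow(x) - 5, "more trials\n")
  invisible(x)
}

#' Write / read a behavioral session as CSV
#'
#' The log format is columnar text with header
#' `participant_id,trial,can_ask,context,first_action,first_observation,second_action,reward,net_reward`,
#' booleans coded 0/1 and contexts coded 1/2.
#'
#' @param x a `"bandit_session"`.
#' @param file path to write to / read from.
#' @param config the [task_config()] used to validate records on read.
#' @return `write_session` returns `file` invisibly; `read_session` returns a
#'   `"bandit_session"`.
#' @export
write_session <- function(x, file) {
  out <- as.data.frame(x)
  out$can_ask <- as.integer(out$can_ask)
  utils::write.csv(out, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_session
#' @export
read_session <- function(file, config = task_config()) {
  df <- utils::read.csv(file, stringsAsFactors = FALSE)
  df$can_ask <- as.logical(df$can_ask)
  df$context <- as.integer(df$context)
  df$trial <- as.integer(df$trial)
  df$reward <- as.numeric(df$reward)
  df$net_reward <- as.numeric(df$net_reward)
  as_bandit_session(df, config)
}

#' Serialize a task configuration as JSON
#'
#' @param config a [task_config()].
#' @param file path to a JSON file.
#' @return `write_task_config` returns `file` invisibly; `read_task_config`
#'   returns a [task_config()].
#' @export
write_task_config <- function(config, file) {
  jsonlite::write_json(unclass(config), file, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(file)
}

#' @rdname write_task_config
#' @export
read_task_config <- function(file) {
  x <- jsonlite::read_json(file, simplifyVector = TRUE)
  do.call(task_config, x)
}
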