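#' Generative model of the active inference agent
#'
#' Builds the agent's internal POMDP model of the task: a Dirichlet
#' concentration array `a` over the likelihood mapping, the per-action
#' transition matrices `B`, log preferences over outcomes `logC`, and the
#' initial-state prior `d`, together with the policy-value coefficients.
#'
#' The hidden state space factorises as
#' \{Start, Cued, ChoseSafe, ChoseRisky\} x \{Context 1, Context 2\}
#' (8 states). Observations are \{Null, Cue1, Cue2, R0, R3, R6, R9, R12\}
#' (8 outcomes); with `merge_null = TRUE` the Null outcome is merged into R0,
#' giving a 7-outcome variant. Deterministic state-outcome mappings
#' (Start -> Null, Cued -> matching cue, ChoseSafe -> safe reward) carry unit
#' concentration on the true cell; the two ChoseRisky columns carry the free
#' parameter `prior` on every reward outcome and are the only cells the agent
#' learns. Exact zeros in `a` are replaced by a soft floor of 1e-16 so all
#' logarithms stay finite.
#'
#' Log preferences are proportional to monetary value:
#' `logC = preference_scale * value(o)` with value 0 for Null, the cue cost
#' for cues and the reward in apples for reward outcomes. The scale (nats
#' per apple) fixes the exchange rate between information and reward; see
#' the package vignette for the rationale behind the 0.25 default.
#'
#' @param prior positive initial concentration of the learnable (risky)
#'   likelihood cells; the `prior` free parameter of the model.
#' @param AL,AI,EX nonnegative coefficients scaling the value of reducing
#'   novelty, the value of reducing variability, and extrinsic value in the
#'   expected free energy.
#' @param alpha learning rate (>= 0) of the Dirichlet concentration update.
#' @param gamma precision (inverse temperature, > 0) of policy selection.
#' @param config a [task_config()] describing the task the model is for.
#' @param preference_scale nats per apple used to build `logC`.
#' @param merge_null merge the Null outcome into R0 (7-outcome variant).
#' @return an object of class `"aif_model"`.
#' @examples
#' m <- aif_model(prior = 0.5)
#' normalize_likelihood(m$a)[, "ChoseRisky.Ctx1"]
#' @export
aif_model <- function(prior = 0.25, AL = 1, AI = 1, EX = 1, alpha = 1,
                      gamma = 4, config = task_config(),
                      preference_scale = 0.25, merge_null = FALSE) {
  if (!is.numeric(prior) || prior <= 0) stop("invalid parameter: prior must be > 0")
  if (alpha < 0) stop("invalid parameter: alpha must be >= 0")
  if (gamma <= 0) stop("invalid parameter: gamma must be > 0")
  if (AL < 0 || AI < 0 || EX < 0) {
    stop("invalid parameter: AL, AI, EX must be >= 0")
  }

  rv <- config$reward_values
  states <- c("Start.Ctx1", "Start.Ctx2", "Cued.Ctx1", "Cued.Ctx2",
              "ChoseSafe.Ctx1", "ChoseSafe.Ctx2",
              "ChoseRisky.Ctx1", "ChoseRisky.Ctx2")
  robs <- paste0("R", rv)
  obs <- if (merge_null) c("Cue1", "Cue2", robs) else c("Null", "Cue1", "Cue2", robs)
  i_cue <- match(c("Cue1", "Cue2"), obs)
  i_rewards <- match(robs, obs)
  i_null <- if (merge_null) i_rewards[1L] else match("Null", obs)
  i_safe <- i_rewards[match(config$safe_reward, rv)]

  a <- matrix(.LOG_FLOOR, nrow = length(obs), ncol = length(states),
              dimnames = list(obs, states))
  a[i_null, c("Start.Ctx1", "Start.Ctx2")] <- 1
  a[i_cue[1L], "Cued.Ctx1"] <- 1
  a[i_cue[2L], "Cued.Ctx2"] <- 1
  a[i_safe, c("ChoseSafe.Ctx1", "ChoseSafe.Ctx2")] <- 1
  a[i_rewards, c("ChoseRisky.Ctx1", "ChoseRisky.Ctx2")] <- prior

  # Transitions: context always persists; actions move the stage factor.
  B <- list()
  eye <- diag(length(states))
  dimnames(eye) <- list(states, states)
  B$Stay <- eye
  B$Cue <- eye
  B$Cue[, c("Start.Ctx1", "Start.Ctx2")] <- 0
  B$Cue["Cued.Ctx1", "Start.Ctx1"] <- 1
  B$Cue["Cued.Ctx2", "Start.Ctx2"] <- 1
  to_stage <- function(stage) {
    m <- matrix(0, length(states), length(states),
                dimnames = list(states, states))
    ctx <- rep(1:2, times = 4)  # context index of each state
    for (j in seq_along(states)) m[paste0(stage, ".Ctx", ctx[j]), j] <- 1
    m
  }
  B$Safe <- to_stage("ChoseSafe")
  B$Risky <- to_stage("ChoseRisky")

  logC <- numeric(length(obs))
  logC[i_cue] <- config$cue_cost
  logC[i_rewards] <- rv
  if (!merge_null) logC[i_null] <- 0
  logC <- preference_scale * logC
  names(logC) <- obs

  d <- numeric(length(states))
  names(d) <- states
  d["Start.Ctx1"] <- config$p_context1
  d["Start.Ctx2"] <- 1 - config$p_context1

  policies <- rbind(CueSafe  = c("Cue", "Safe"),
                    CueRisky = c("Cue", "Risky"),
                    StaySafe = c("Stay", "Safe"),
                    StayRisky = c("Stay", "Risky"))
  colnames(policies) <- c("u1", "u2")

  structure(
    list(a = a, B = B, logC = logC, d = d,
         pars = list(AL = AL, AI = AI, EX = EX, alpha = alpha, gamma = gamma,
                     prior = prior, preference_scale = preference_scale),
         policies = policies,
         idx = list(null = i_null, cue = i_cue, rewards = i_rewards,
                    safe_obs = i_safe,
                    s_start = 1:2, s_cued = 3:4, s_safe = 5:6, s_risky = 7:8),
         config = config, merge_null = merge_null,
         states = states, observations = obs),
    class = "aif_model"
  )
}

#' @export
print.aif_model <- function(x, ...) {
  p <- x$pars
  cat("Active inference generative model\n")
  cat(sprintf("  %d hidden states x %d observations, 4 policies\n",
              length(x$states), length(x$observations)))
  cat(sprintf("  AL = %g, AI = %g, EX = %g, prior = %g, alpha = %g, gamma = %g\n",
              p$AL, p$AI, p$EX, p$prior, p$alpha, p$gamma))
  cat(sprintf("  preference scale: %g nats/apple\n", p$preference_scale))
  invisible(x)
}

#' Dirichlet mean of a concentration array
#'
#' Normalizes each column of a concentration array to the expected
#' likelihood `A = Cat(a)` (entries divided by their column sum).
#'
#' @param a nonnegative matrix, observations x hidden states, with positive
#'   column sums.
#' @return column-stochastic matrix of the same shape.
#' @export
normalize_likelihood <- function(a) {
  cs <- colSums(a)
  if (any(cs <= 0)) stop("degenerate column: zero concentration sum")
  sweep(a, 2, cs, "/")
}

#' Dirichlet concentration update after an observation
#'
#' Implements `a' = a + alpha * (o %o% q)`: the outer product of the
#' observed outcome with the state posterior, scaled by the learning rate,
#' is added to the concentration array (cumulative counting of
#' state-outcome co-occurrences).
#'
#' @param a concentration matrix, observations x states.
#' @param observation observed outcome: an index, an outcome label, or a
#'   one-hot vector over rows of `a`.
#' @param state_posterior probability vector over states (columns of `a`).
#' @param alpha learning rate (>= 0).
#' @return updated concentration matrix.
#' @export
update_concentrations <- function(a, observation, state_posterior, alpha) {
  if (!is.numeric(alpha) || alpha < 0) {
    stop("invalid parameter: alpha must be >= 0")
  }
  if (is.character(observation)) observation <- match(observation, rownames(a))
  if (length(observation) > 1L) {
    if (sum(observation == 1) != 1L || sum(observation) != 1) {
      stop("observation must be one-hot")
    }
    observation <- which(observation == 1)
  }
  if (is.na(observation) || observation < 1 || observation > nrow(a)) {
    stop("unknown observation")
  }
  if (!.is_prob_vector(state_posterior)) {
    stop("state_posterior must sum to 1")
  }
  a[observation, ] <- a[observation, ] + alpha * state_posterior
  a
}

#' Expected reward of the risky path under the agent's beliefs
#'
#' Computes the mean reward the agent currently attributes to the risky
#' path in a given context, i.e. the reward-weighted Dirichlet mean of the
#' corresponding likelihood column.
#'
#' @param model an [aif_model()].
#' @param context integer context (1 or 2).
#' @return expected reward in apples.
#' @export
expected_risky_reward <- function(model, context) {
  A <- normalize_likelihood(model$a)
  col <- A[, model$idx$s_risky[context]]
  sum(model$config$reward_values * col[model$idx$rewards])
}

#' Snapshot a generative model to JSON
#'
#' Serializes labels, concentrations, transitions, preferences and
#' parameters so a fitted or simulated model can be reproduced exactly.
#'
#' @param model an [aif_model()].
#' @param file path to a JSON file.
#' @return `model_to_json` returns `file` invisibly; `model_from_json`
#'   returns an `"aif_model"`.
#' @export
model_to_json <- function(model, file) {
  snap <- list(
    pars = model$pars, merge_null = model$merge_null,
    config = unclass(model$config),
    a = model$a, states = model$states, observations = model$observations
  )
  jsonlite::write_json(snap, file, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(file)
}

#' @rdname model_to_json
#' @export
model_from_json <- function(file) {
  snap <- jsonlite::read_json(file, simplifyVector = TRUE)
  cfg <- do.call(task_config, snap$config)
  m <- do.call(aif_model, c(snap$pars[c("prior", "AL", "AI", "EX", "alpha",
                                        "gamma", "preference_scale")],
                            list(config = cfg, merge_null = snap$merge_null)))
  a <- as.matrix(snap$a)
  dimnames(a) <- dimnames(m$a)
  m$a <- a
  m
}
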