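# Belief updating and policy evaluation: exact state inference, variational
# free energy, and the expected free energy decomposition into the value of
# reducing novelty, the value of reducing variability, and extrinsic value.

# Per-trial precomputation from the current concentration array. For a unit
# Dirichlet update a -> a + e_o in column s, the KL divergence from posterior
# to prior reduces to log(a0) - log(a_os) + digamma(a_os + 1) - digamma(a0 + 1)
# where a0 is the column sum, so the whole observation x state KL table is a
# single vectorized expression.
.aif_precompute <- function(model) {
  a <- model$a
  cs <- colSums(a)
  A <- sweep(a, 2, cs, "/")
  lnA <- .safe_log(A)
  KL <- sweep(digamma(a + 1) - log(a), 2, log(cs) - digamma(cs + 1), "+")
  list(A = A, lnA = lnA,
       w = colSums(A * KL),          # expected parameter info gain per state
       h = -colSums(A * lnA),        # outcome entropy per state
       u = drop(crossprod(A, model$logC)))  # expected log preference per state
}

# Raw per-slot terms of the expected free energy for a matrix of predicted
# state distributions QS (states x slots). Returns the uncoefficiented
# novelty, salience and extrinsic components; novelty and salience are
# negated expected information gains, hence <= 0.
.slot_terms <- function(QS, pre) {
  QO <- pre$A %*% QS
  list(nov = -drop(crossprod(QS, pre$w)),
       sal = drop(crossprod(QS, pre$h)) + colSums(QO * .safe_log(QO)),
       ext = drop(crossprod(QS, pre$u)))
}

.decomp <- function(nov, sal, ext, pars) {
  nv <- pars$AL * nov
  vv <- pars$AI * sal
  ev <- pars$EX * ext
  list(raw_novelty = nov, raw_salience = sal, raw_extrinsic = ext,
       novelty_value = nv, variability_value = vv, extrinsic_value = ev,
       G = nv + vv - ev)
}

# Expected free energy of all four policies over the within-trial horizon
# (tau = 1, 2), from the trial-start belief q0. Policy order: CueSafe,
# CueRisky, StaySafe, StayRisky.
.stage1_policy_terms <- function(q0, pre, model) {
  B <- model$B
  q_cue <- B$Cue %*% q0
  QS <- cbind(q0, q_cue,                       # tau = 1 under Stay / Cue
              B$Safe %*% q_cue, B$Risky %*% q_cue,
              B$Safe %*% q0, B$Risky %*% q0)   # tau = 2 per policy
  tt <- .slot_terms(QS, pre)
  s1 <- c(2L, 2L, 1L, 1L)  # tau-1 slot per policy
  s2 <- c(3L, 4L, 5L, 6L)
  d <- .decomp(tt$nov[s1] + tt$nov[s2], tt$sal[s1] + tt$sal[s2],
               tt$ext[s1] + tt$ext[s2], model$pars)
  d$names <- rownames(model$policies)
  d
}

# Remaining-horizon expected free energy at the second choice, from the
# post-observation belief q1. Slots: Safe, Risky.
.stage2_policy_terms <- function(q1, pre, model) {
  QS <- cbind(model$B$Safe %*% q1, model$B$Risky %*% q1)
  tt <- .slot_terms(QS, pre)
  d <- .decomp(tt$nov, tt$sal, tt$ext, model$pars)
  d$names <- c("Safe", "Risky")
  d
}

.belief_update <- function(q, action, obs_index, A, B) {
  qp <- drop(B[[action]] %*% q)
  post <- A[obs_index, ] * qp
  s <- sum(post)
  if (s < 1e-14) stop("impossible observation under every hidden state")
  post / s
}

#' Exact posterior over hidden states given an action-observation history
#'
#' Runs exact Bayesian filtering over the small discrete state space: the
#' prior `d` is propagated through the transition of each realized action
#' and conditioned on each observation. On this model family the filter
#' attains the variational minimum, so the result equals the brute-force
#' enumeration posterior.
#'
#' @param model an [aif_model()].
#' @param observations character vector of observed outcome labels.
#' @param actions character vector of realized actions, same length.
#' @return named probability vector over the hidden states at the final
#'   step.
#' @examples
#' m <- aif_model()
#' infer_states(m, "Cue1", "Cue")  # context resolved
#' @export
infer_states <- function(model, observations, actions) {
  if (length(observations) != length(actions)) {
    stop("observations and actions must have equal length")
  }
  A <- normalize_likelihood(model$a)
  q <- model$d
  for (t in seq_along(actions)) {
    o <- match(observations[t], model$observations)
    if (is.na(o)) stop("unknown observation label: ", observations[t])
    if (!actions[t] %in% names(model$B)) {
      stop("invalid action: ", actions[t])
    }
    q <- .belief_update(q, actions[t], o, A, model$B)
  }
  q
}

#' Variational free energy of an approximate state posterior
#'
#' Evaluates `F = KL(q || prior) - E_q[ln P(o | s)]`, the complexity-minus-
#' accuracy form. `F` upper-bounds the negative log evidence `-ln P(o)`,
#' with equality exactly at the true posterior.
#'
#' @param q probability vector over hidden states.
#' @param model an [aif_model()].
#' @param observation outcome label or row index.
#' @param prior probability vector over states (defaults to the model's
#'   initial-state prior `d`).
#' @return free energy in nats.
#' @export
variational_free_energy <- function(q, model, observation, prior = model$d) {
  if (!.is_prob_vector(q)) stop("q must sum to 1")
  A <- normalize_likelihood(model$a)
  if (is.character(observation)) {
    observation <- match(observation, model$observations)
  }
  lik <- A[observation, ]
  sum(q * (.safe_log(q) - .safe_log(prior))) - sum(q * .safe_log(lik))
}

#' Expected free energy of a policy, decomposed
#'
#' Computes the expected free energy of one policy at one within-trial time
#' step (or summed over the horizon), decomposed into the value of reducing
#' novelty (`AL` times the negated expected information gain about the
#' likelihood Dirichlet parameters), the value of reducing variability
#' (`AI` times the negated expected information gain about the hidden
#' states), and extrinsic value (`EX` times the expected log preference of
#' outcomes): `G = novelty_value + variability_value - extrinsic_value`.
#'
#' The parameter information gain is evaluated exactly by enumerating the
#' candidate observations and applying the closed-form Dirichlet KL of a
#' unit update; the state information gain is the mutual information
#' between predicted states and outcomes.
#'
#' @param model an [aif_model()].
#' @param belief probability vector over hidden states at the start of the
#'   trial (defaults to the model prior `d`).
#' @param policy policy name (`"CueSafe"`, `"CueRisky"`, `"StaySafe"`,
#'   `"StayRisky"`) or index.
#' @param tau within-trial time step (1 or 2), or `NULL` to sum the
#'   horizon.
#' @return an object of class `"efe"`: a list with the coefficiented values,
#'   the raw (uncoefficiented, nonpositive) novelty and salience terms, and
#'   `total_G`.
#' @examples
#' m <- aif_model()
#' expected_free_energy(m, policy = "CueRisky")
#' @export
expected_free_energy <- function(model, belief = model$d, policy, tau = NULL) {
  if (!.is_prob_vector(belief)) stop("belief must sum to 1")
  if (is.character(policy)) policy <- match(policy, rownames(model$policies))
  if (is.na(policy) || policy < 1 || policy > nrow(model$policies)) {
    stop("unknown policy")
  }
  pre <- .aif_precompute(model)
  acts <- model$policies[policy, ]
  q <- belief
  QS <- matrix(0, length(q), 2L)
  for (k in 1:2) {
    q <- drop(model$B[[acts[k]]] %*% q)
    QS[, k] <- q
  }
  keep <- if (is.null(tau)) 1:2 else {
    if (!tau %in% 1:2) stop("tau must be 1 or 2")
    tau
  }
  tt <- .slot_terms(QS[, keep, drop = FALSE], pre)
  d <- .decomp(sum(tt$nov), sum(tt$sal), sum(tt$ext), model$pars)
  structure(list(policy = rownames(model$policies)[policy], tau = tau,
                 novelty_value = d$novelty_value,
                 variability_value = d$variability_value,
                 extrinsic_value = d$extrinsic_value,
                 total_G = d$G,
                 raw_novelty = d$raw_novelty,
                 raw_salience = d$raw_salience),
            class = "efe")
}

#' @export
print.efe <- function(x, ...) {
  cat(sprintf("Expected free energy, policy %s%s\n", x$policy,
              if (is.null(x$tau)) " (horizon)" else paste0(", tau = ", x$tau)))
  cat(sprintf("  G = %.6f = %.6f (novelty) + %.6f (variability) - %.6f (extrinsic)\n",
              x$total_G, x$novelty_value, x$variability_value,
              x$extrinsic_value))
  cat(sprintf("  raw novelty %.6f, raw salience %.6f\n",
              x$raw_novelty, x$raw_salience))
  invisible(x)
}

#' Expected free energy of all four policies
#'
#' Horizon-summed decomposition for every policy, as a data frame.
#'
#' @inheritParams expected_free_energy
#' @return data frame with one row per policy and columns `G`,
#'   `novelty_value`, `variability_value`, `extrinsic_value`,
#'   `raw_novelty`, `raw_salience`.
#' @export
efe_policies <- function(model, belief = model$d) {
  if (!.is_prob_vector(belief)) stop("belief must sum to 1")
  pre <- .aif_precompute(model)
  d <- .stage1_policy_terms(belief, pre, model)
  data.frame(policy = d$names, G = d$G,
             novelty_value = d$novelty_value,
             variability_value = d$variability_value,
             extrinsic_value = d$extrinsic_value,
             raw_novelty = d$raw_novelty, raw_salience = d$raw_salience,
             row.names = NULL)
}

#' Posterior over policies
#'
#' Softmax of the negated, precision-weighted expected free energies:
#' `Q(pi) = softmax(-gamma * G)`.
#'
#' @param G numeric vector of per-policy expected free energies.
#' @param gamma precision (> 0).
#' @return probability vector over policies.
#' @export
policy_posterior <- function(G, gamma = 1) {
  if (gamma <= 0) stop("invalid parameter: gamma must be > 0")
  .softmax(-gamma * G)
}

#' Marginal action probabilities from a policy posterior
#'
#' At the first stage an action's probability is the total posterior mass
#' of policies prescribing it. At the second stage, policies inconsistent
#' with the realized first action are zeroed and the remainder renormalized
#' before marginalizing.
#'
#' @param q_policy probability vector over the four policies, ordered
#'   CueSafe, CueRisky, StaySafe, StayRisky.
#' @param stage `"first"` or `"second"`.
#' @param first_action realized first-stage action (required at the second
#'   stage).
#' @return named probability vector over the stage's available actions.
#' @export
action_marginal <- function(q_policy, stage = c("first", "second"),
                            first_action = NULL) {
  stage <- match.arg(stage)
  if (length(q_policy) != 4L || !.is_prob_vector(q_policy)) {
    stop("q_policy must be a probability vector over the 4 policies")
  }
  q_policy <- unname(q_policy)
  if (stage == "first") {
    c(Stay = q_policy[3L] + q_policy[4L], Cue = q_policy[1L] + q_policy[2L])
  } else {
    if (is.null(first_action)) stop("first_action required at stage 'second'")
    keep <- if (first_action == "Cue") 1:2 else 3:4
    w <- q_policy[keep]
    if (sum(w) <= 0) stop("degenerate policy posterior: no consistent policy has mass")
    w <- w / sum(w)
    c(Safe = w[1L], Risky = w[2L])
  }
}
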