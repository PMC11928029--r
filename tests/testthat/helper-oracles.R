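# Shared fixtures and independent oracles used across the test files.

# Brute-force posterior over the final hidden state by enumerating every
# state path, independent of the package's sequential filter.
enum_posterior <- function(model, observations, actions) {
  A <- sweep(model$a, 2, colSums(model$a), "/")
  S <- length(model$d)
  oidx <- match(observations, model$observations)
  oidx[is.na(oidx) & observations == "Null"] <- model$idx$null
  tmax <- length(actions)
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), tmax)))
  post <- numeric(S)
  for (r in seq_len(nrow(paths))) {
    s <- paths[r, ]
    for (s0 in seq_len(S)) {
      p <- model$d[s0]
      prev <- s0
      for (t in seq_len(tmax)) {
        p <- p * model$B[[actions[t]]][s[t], prev] * A[oidx[t], s[t]]
        prev <- s[t]
      }
      post[s[tmax]] <- post[s[tmax]] + p
    }
  }
  post / sum(post)
}

# Generic Dirichlet KL divergence, written out from the closed form.
dkl_dirichlet <- function(a1, a0) {
  lgamma(sum(a1)) - lgamma(sum(a0)) - sum(lgamma(a1) - lgamma(a0)) +
    sum((a1 - a0) * (digamma(a1) - digamma(sum(a1))))
}

# Random probability vector on the simplex.
rsimplex <- function(k) {
  x <- stats::rexp(k)
  x / sum(x)
}

# A model with randomized concentrations, belief and coefficients, for
# property-style checks of the expected free energy machinery.
random_model <- function() {
  m <- aif_model(prior = stats::runif(1, 0.05, 3),
                 AL = stats::runif(1, 0, 3),
                 AI = stats::runif(1, 0, 3),
                 EX = stats::runif(1, 0, 3),
                 alpha = stats::runif(1),
                 gamma = stats::runif(1, 0.5, 5))
  m$a <- matrix(stats::runif(length(m$a), 0.01, 5), nrow(m$a), ncol(m$a),
                dimnames = dimnames(m$a))
  m
}

# Hand-built two-trial session used by the likelihood oracles.
two_trial_session <- function(config = task_config()) {
  as_bandit_session(
    data.frame(
      participant_id = "fix", trial = 1:2, can_ask = c(TRUE, TRUE),
      context = c(1L, 2L), first_action = c("Cue", "Stay"),
      first_observation = c("Cue1", "Null"),
      second_action = c("Risky", "Safe"), reward = c(12, 6),
      net_reward = c(11, 6), stringsAsFactors = FALSE),
    config
  )
}
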