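# Belief updating and policy evaluation: exact posteriors, the free energy
# bound, and the expected free energy decomposition.

test_that("state inference matches brute-force enumeration on all reachable histories", {
  m <- aif_model(prior = 0.8)
  m$a["R9", "ChoseRisky.Ctx1"] <- 2.5        # make the columns informative
  m$a["R0", "ChoseRisky.Ctx2"] <- 3.1
  cfg <- m$config
  rlabels <- paste0("R", cfg$reward_values)
  histories <- list()
  for (u2 in c("Safe", "Risky")) {
    o2s <- if (u2 == "Safe") "R6" else rlabels
    for (o2 in o2s) {
      histories[[length(histories) + 1]] <-
        list(obs = c("Cue1", o2), act = c("Cue", u2))
      histories[[length(histories) + 1]] <-
        list(obs = c("Cue2", o2), act = c("Cue", u2))
      histories[[length(histories) + 1]] <-
        list(obs = c("Null", o2), act = c("Stay", u2))
    }
  }
  for (h in histories) {
    q <- infer_states(m, h$obs, h$act)
    expect_equal(unname(q), enum_posterior(m, h$obs, h$act),
                 tolerance = 1e-10)
  }
})

test_that("inference handles uninformative, decisive and impossible evidence", {
  m <- aif_model()
  # a Null observation at the start leaves the context belief at the prior
  q <- infer_states(m, "Null", "Stay")
  expect_equal(unname(q[c("Start.Ctx1", "Start.Ctx2")]), c(0.5, 0.5),
               tolerance = 1e-9)
  # a cue resolves the context completely
  q <- infer_states(m, "Cue1", "Cue")
  expect_equal(unname(q["Cued.Ctx1"]), 1, tolerance = 1e-9)
  # a cue observation without having asked is impossible
  expect_error(infer_states(m, "Cue1", "Stay"), "impossible observation")
})

test_that("variational free energy matches a hand-evaluated two-state toy", {
  toy <- list(a = matrix(c(0.9, 0.1, 0.1, 0.9), 2, 2), observations = 1:2,
              d = c(0.5, 0.5))
  q <- c(0.8, 0.2); prior <- c(0.5, 0.5); lik <- c(0.9, 0.1)
  by_hand <- sum(q * log(q / prior)) - sum(q * log(lik))
  expect_equal(variational_free_energy(q, toy, 1, prior), by_hand,
               tolerance = 1e-12)
})

test_that("free energy bounds negative log evidence, with equality at the posterior", {
  m <- aif_model(prior = 0.6)
  obs <- "R9"; action <- "Risky"
  prior_states <- as.numeric(m$B[[action]] %*% m$d)
  A <- normalize_likelihood(m$a)
  evidence <- sum(A[match(obs, m$observations), ] * prior_states)
  posterior <- infer_states(m, obs, action)
  expect_equal(variational_free_energy(posterior, m, obs, prior_states),
               -log(evidence), tolerance = 1e-10)
  set.seed(10)
  for (i in 1:1000) {
    q <- rsimplex(8)
    f <- variational_free_energy(q, m, obs, prior_states)
    expect_gte(f, -log(evidence) - 1e-12)
  }
})

test_that("expected free energy reproduces exact epistemic-value oracles", {
  # zero coefficients zero the total for every policy
  m0 <- aif_model(AL = 0, AI = 0, EX = 0)
  ep <- efe_policies(m0)
  expect_equal(ep$G, rep(0, 4), tolerance = 1e-12)

  # asking under an uninformative context belief is worth exactly one bit
  m <- aif_model(AI = 1)
  e <- expected_free_energy(m, policy = "CueSafe", tau = 1)
  expect_equal(e$variability_value, -log(2), tolerance = 1e-9)
  expect_equal(e$raw_salience, -log(2), tolerance = 1e-9)

  # a fully known likelihood yields (numerically) no novelty
  mBig <- aif_model(prior = 1e6)
  e2 <- expected_free_energy(mBig, policy = "StayRisky", tau = 2)
  expect_lt(abs(e2$raw_novelty), 1e-3)

  # exact novelty equals the observation-enumerated Dirichlet KL oracle
  m3 <- aif_model(prior = 0.4)
  e3 <- expected_free_energy(m3, policy = "StayRisky", tau = 2)
  A <- normalize_likelihood(m3$a)
  col <- 7:8
  nov <- 0
  for (s in col) {
    for (o in seq_len(nrow(m3$a))) {
      w <- A[o, s] * 0.5                     # P(o, s) under the policy
      a1 <- m3$a[, s]; a1[o] <- a1[o] + 1
      nov <- nov - w * dkl_dirichlet(a1, m3$a[, s])
    }
  }
  expect_equal(e3$raw_novelty, nov, tolerance = 1e-9)
})

test_that("the decomposition is additive and its epistemic terms are nonpositive", {
  set.seed(12)
  for (i in 1:200) {
    m <- random_model()
    belief <- rsimplex(8)
    ep <- efe_policies(m, belief)
    expect_equal(ep$G,
                 m$pars$AL * ep$raw_novelty + m$pars$AI * ep$raw_salience -
                   ep$extrinsic_value, tolerance = 1e-10)
    expect_true(all(ep$raw_novelty <= 1e-12))
    expect_true(all(ep$raw_salience <= 1e-12))
  }
})

test_that("policy posterior is the precision-weighted softmax", {
  expect_equal(policy_posterior(rep(-1.3, 4)), rep(0.25, 4))
  expect_equal(policy_posterior(c(-2, -1), gamma = 1),
               c(exp(2), exp(1)) / (exp(2) + exp(1)), tolerance = 1e-10)
  expect_equal(round(policy_posterior(c(-2, -1), 1), 4), c(0.7311, 0.2689))
  g <- c(-1.0, -0.9, -0.5, 0)
  expect_gt(policy_posterior(g, gamma = 200)[1], 1 - 1e-6)
  expect_error(policy_posterior(g, gamma = 0), "invalid parameter")
})

test_that("action marginals aggregate and renormalize policy mass", {
  q <- c(0.4, 0.3, 0.2, 0.1)  # CueSafe, CueRisky, StaySafe, StayRisky
  expect_equal(action_marginal(rep(0.25, 4), "first"),
               c(Stay = 0.5, Cue = 0.5))
  expect_equal(action_marginal(q, "first"), c(Stay = 0.3, Cue = 0.7))
  expect_equal(action_marginal(q, "second", first_action = "Stay"),
               c(Safe = 2 / 3, Risky = 1 / 3), tolerance = 1e-12)
  expect_error(action_marginal(c(0.5, 0.5, 0, 0), "second",
                               first_action = "Stay"),
               "degenerate policy")
  expect_error(action_marginal(q, "second"), "first_action")
})

test_that("stronger variability coefficients monotonically favor asking", {
  p_cue <- vapply(c(0, 0.5, 1, 2, 4), function(ai) {
    m <- aif_model(AI = ai, gamma = 1)
    g <- efe_policies(m)$G
    unname(action_marginal(policy_posterior(g, 1), "first")["Cue"])
  }, numeric(1))
  expect_true(all(diff(p_cue) > 0))
})
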