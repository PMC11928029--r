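# Trial-wise regressors and the mass-univariate regression machinery.

test_that("regressor tables carry the decomposition and realized updates", {
  cfg <- task_config(n_trials = 30, p_can_ask = 1)
  tr <- run_agent(list(AL = 0.7, AI = 1.2, EX = 1, prior = 0.5, alpha = 0.8),
                  cfg, seed = 41)
  reg <- compute_regressors(tr)
  expect_equal(nrow(reg), 30 * 4)
  ch <- reg[reg$stage %in% c("first_choice", "second_choice"), ]
  expect_equal(ch$expected_free_energy,
               ch$value_of_reducing_novelty + ch$value_of_reducing_variability -
                 ch$extrinsic_value, tolerance = 1e-10)
  # asking resolves one bit of state uncertainty at the first result
  fr <- reg[reg$stage == "first_result", ]
  cue_trials <- tr$trials$first_action == "Cue"
  expect_equal(abs(fr$reducing_variability[cue_trials]) / 1.2,
               rep(log(2), sum(cue_trials)), tolerance = 1e-6)
  expect_equal(fr$reducing_variability[!cue_trials],
               rep(0, sum(!cue_trials)), tolerance = 1e-6)
  # realized novelty reduction is nonpositive and reward rows are filled
  sr <- reg[reg$stage == "second_result", ]
  expect_true(all(sr$reducing_novelty <= 1e-12))
  expect_equal(sr$reward, tr$trials$reward)
  expect_equal(sr$prediction_error, tr$trials$pe)
})

test_that("a zero novelty coefficient zeroes its value column", {
  tr <- run_agent(list(AL = 0), task_config(n_trials = 15), seed = 2)
  reg <- compute_regressors(tr)
  ch <- reg[reg$stage %in% c("first_choice", "second_choice"), ]
  expect_equal(ch$value_of_reducing_novelty, rep(0, nrow(ch)))
})

test_that("replaying a session reproduces the generative trace's regressors", {
  cfg <- task_config(n_trials = 20)
  params <- list(AL = 1, AI = 1, EX = 1, prior = 0.5, alpha = 1)
  tr <- run_agent(params, cfg, seed = 77)
  reg1 <- compute_regressors(tr)
  reg2 <- compute_regressors(trace_to_session(tr), params = params)
  expect_equal(as.data.frame(reg1), as.data.frame(reg2), tolerance = 1e-12)
  expect_error(compute_regressors(trace_to_session(tr)), "incomplete trace")
})

test_that("OLS matches closed-form and lm on fixtures", {
  # three-point closed form
  y <- array(c(1, 3, 5), dim = c(3, 1, 1))
  res <- mass_univariate_regression(y, c(0, 1, 2), zscore = FALSE)
  expect_equal(res$beta[1, 1], 2, tolerance = 1e-12)
  expect_equal(res$intercept[1, 1], 1, tolerance = 1e-12)
  # activity identical to the regressor: unit slope, zero residuals
  x <- rnorm(25)
  res2 <- mass_univariate_regression(array(x, dim = c(25, 1, 1)), x,
                                     zscore = FALSE)
  expect_equal(res2$beta[1, 1], 1, tolerance = 1e-12)
  expect_equal(res2$p[1, 1], 0)
  # dual route: vectorized fit equals stats::lm cell by cell
  set.seed(30)
  act <- array(rnorm(20 * 2 * 3), dim = c(20, 2, 3))
  x <- rnorm(20)
  res3 <- mass_univariate_regression(act, x, zscore = FALSE)
  for (r in 1:2) for (tp in 1:3) {
    fit <- summary(stats::lm(act[, r, tp] ~ x))
    expect_equal(res3$beta[r, tp], fit$coefficients["x", "Estimate"],
                 tolerance = 1e-10)
    expect_equal(res3$t[r, tp], fit$coefficients["x", "t value"],
                 tolerance = 1e-10)
    expect_equal(res3$p[r, tp], fit$coefficients["x", "Pr(>|t|)"],
                 tolerance = 1e-10)
  }
  expect_error(mass_univariate_regression(act, rep(1, 20)),
               "degenerate design")
  expect_error(mass_univariate_regression(act, x[1:5]), "trial count")
})

test_that("permuted regressors are calibrated against structured activity", {
  set.seed(31)
  n <- 60
  y <- array(rnorm(n) + seq_len(n) / n, dim = c(n, 1, 1))
  x <- rnorm(n)
  pvals <- vapply(1:1000, function(i) {
    mass_univariate_regression(y, sample(x))$p[1, 1]
  }, numeric(1))
  expect_lt(abs(mean(pvals < 0.05) - 0.05), 3 * sqrt(0.05 * 0.95 / 1000))
})

test_that("t and p are invariant to affine regressor rescaling", {
  set.seed(32)
  act <- array(rnorm(30 * 2 * 4), dim = c(30, 2, 4))
  x <- rnorm(30)
  a <- mass_univariate_regression(act, x, zscore = FALSE)
  b <- mass_univariate_regression(act, 3.7 * x + 2, zscore = FALSE)
  expect_equal(a$t, b$t, tolerance = 1e-8)
  expect_equal(a$p, b$p, tolerance = 1e-8)
  expect_equal(a$beta, b$beta * 3.7, tolerance = 1e-8)
})

test_that("Benjamini-Hochberg rejects by the step-up rule", {
  expect_equal(fdr_correct(rep(1, 6)), rep(FALSE, 6))
  expect_equal(fdr_correct(c(0.001, 0.01, 0.02, 0.5), q = 0.05),
               c(TRUE, TRUE, TRUE, FALSE))
  expect_identical(fdr_correct(numeric(0)), logical(0))
  m <- matrix(c(0.001, 0.8, 0.004, 0.9), 2, 2)
  mask <- fdr_correct(m, q = 0.05)
  expect_equal(dim(mask), c(2L, 2L))
  # monotone: rejecting p_i implies rejecting every smaller p
  set.seed(33)
  p <- runif(50)
  mask <- fdr_correct(p, 0.1)
  if (any(mask)) expect_true(all(mask[p <= max(p[mask])]))
  expect_error(fdr_correct(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("planted-effect discoveries control the false discovery proportion", {
  set.seed(34)
  x <- rnorm(100)
  fdp <- vapply(1:50, function(i) {
    ep <- generate_neural_epochs(x, beta_true = 0.6, noise_sd = 1,
                                 n_regions = 3, n_timepoints = 20,
                                 seed = 200 + i)
    res <- mass_univariate_regression(ep, x, q = 0.05)
    truth <- matrix(FALSE, 3, 20)
    truth[ep$truth$effect_region, ep$truth$effect_window] <- TRUE
    n_disc <- sum(res$fdr_mask)
    if (n_disc == 0) 0 else sum(res$fdr_mask & !truth) / n_disc
  }, numeric(1))
  expect_lte(mean(fdp), 0.05 + 0.05)
})

test_that("regressor tables serialize to CSV", {
  tr <- run_agent(config = task_config(n_trials = 5), seed = 1)
  reg <- compute_regressors(tr)
  f <- tempfile(fileext = ".csv")
  write_regressors(reg, f)
  back <- utils::read.csv(f)
  expect_equal(nrow(back), nrow(reg))
  expect_equal(back$expected_free_energy, reg$expected_free_energy,
               tolerance = 1e-6)
})
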