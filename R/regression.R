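# Trial-wise model regressors and the mass-univariate regression with
# false discovery rate correction.

#' Trial-wise model regressors for neural analysis
#'
#' Builds the per-trial, per-stage regressor table used to interrogate
#' neural time series. Choice-stage rows carry the chosen action's
#' policy-evaluated expected free energy decomposition (for the first
#' choice, the posterior-weighted average over the two policies consistent
#' with the chosen action; for the second choice, the evaluated remaining
#' horizon of the taken policy). Result-stage rows carry realized
#' belief-update quantities: at the first result the value of the realized
#' reduction in state uncertainty (`AI` times the negated KL from the
#' post-observation to the pre-observation state belief), and at the
#' second result the realized reduction in parameter uncertainty (negated
#' Dirichlet KL of the concentration update), the reward, and the reward
#' prediction error.
#'
#' @param x an `"aif_trace"` from [run_agent()], or a `"bandit_session"`
#'   to be replayed under `params`.
#' @param params named active inference parameters, required when `x` is a
#'   session (typically `coef()` of a fitted model).
#' @param config task configuration for the replay; defaults to the
#'   session's own.
#' @return a data frame of class `"regressor_table"` with columns `trial`,
#'   `stage` (first_choice, first_result, second_choice, second_result),
#'   `expected_free_energy`, `value_of_reducing_novelty`,
#'   `value_of_reducing_variability`, `extrinsic_value`, `raw_novelty`,
#'   `raw_salience`, `reducing_variability`, `reducing_novelty`, `reward`,
#'   `prediction_error`; fields not defined at a stage are `NA`.
#' @examples
#' tr <- run_agent(config = task_config(n_trials = 10), seed = 1)
#' head(compute_regressors(tr))
#' @export
compute_regressors <- function(x, params = NULL, config = NULL) {
  if (inherits(x, "bandit_session")) {
    if (is.null(params)) {
      stop("incomplete trace: supply the model parameters to replay a session")
    }
    if (is.null(config)) config <- attr(x, "config")
    eng <- .aif_engine(params, config, data = x, collect = TRUE)
    trace <- list(trials = eng$trials, stage1_chosen = eng$stage1_chosen,
                  stage2_chosen = eng$stage2_chosen, realized = eng$realized,
                  params = eng$model$pars)
  } else if (inherits(x, "aif_trace")) {
    trace <- x
  } else {
    stop("x must be an aif_trace or a bandit_session")
  }
  if (is.null(trace$stage1_chosen) || is.null(trace$realized)) {
    stop("incomplete trace: belief snapshots are missing")
  }
  tr <- trace$trials
  n <- nrow(tr)
  AI <- trace$params$AI
  empty <- rep(NA_real_, n)
  stage_row <- function(stage, chosen = NULL, reducing_variability = empty,
                        reducing_novelty = empty, reward = empty,
                        prediction_error = empty) {
    data.frame(
      trial = tr$trial, stage = stage,
      expected_free_energy = if (is.null(chosen)) empty else chosen$G,
      value_of_reducing_novelty =
        if (is.null(chosen)) empty else chosen$novelty_value,
      value_of_reducing_variability =
        if (is.null(chosen)) empty else chosen$variability_value,
      extrinsic_value = if (is.null(chosen)) empty else chosen$extrinsic_value,
      raw_novelty = if (is.null(chosen)) empty else chosen$raw_novelty,
      raw_salience = if (is.null(chosen)) empty else chosen$raw_salience,
      reducing_variability = reducing_variability,
      reducing_novelty = reducing_novelty,
      reward = reward, prediction_error = prediction_error,
      stringsAsFactors = FALSE
    )
  }
  out <- rbind(
    stage_row("first_choice", chosen = trace$stage1_chosen),
    stage_row("first_result",
              reducing_variability = AI * -trace$realized$state_info_gain),
    stage_row("second_choice", chosen = trace$stage2_chosen),
    stage_row("second_result",
              reducing_novelty = trace$realized$novelty_reduction,
              reward = tr$reward, prediction_error = tr$pe)
  )
  out <- out[order(out$trial), ]
  rownames(out) <- NULL
  class(out) <- c("regressor_table", "data.frame")
  out
}

#' Write a regressor table as CSV
#'
#' @param x a `"regressor_table"`.
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_regressors <- function(x, file) {
  utils::write.csv(as.data.frame(x), file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' Mass-univariate regression of neural activity on a model regressor
#'
#' Fits, independently for every region x timepoint series, the ordinary
#' least squares model `Activity ~ Regressor + Intercept`, and reports the
#' slope, its t statistic (n - 2 degrees of freedom), the two-sided p
#' value, and the Benjamini-Hochberg significance mask over the flattened
#' region x time grid.
#'
#' @param epochs a `"neural_epochs"` object, or a trials x regions x
#'   timepoints array.
#' @param regressor per-trial regressor values; must have positive
#'   variance and match the trial count.
#' @param q false discovery rate level for the mask.
#' @param zscore standardize the regressor first (default), so slopes are
#'   in activity units per SD of the regressor.
#' @return an object of class `"mass_ols"`: matrices `beta`, `intercept`,
#'   `t`, `p` (regions x timepoints), the logical `fdr_mask`, `q`, `df`.
#' @export
mass_univariate_regression <- function(epochs, regressor, q = 0.05,
                                       zscore = TRUE) {
  act <- if (inherits(epochs, "neural_epochs")) epochs$activity else epochs
  if (length(dim(act)) != 3L) {
    stop("epochs must be a trials x regions x timepoints array")
  }
  n <- dim(act)[1L]
  if (length(regressor) != n) {
    stop("regressor length must match the trial count")
  }
  if (stats::var(regressor) == 0) {
    stop("degenerate design: regressor has zero variance")
  }
  x <- if (zscore) as.numeric(scale(regressor)) else as.numeric(regressor)
  nr <- dim(act)[2L]; nt <- dim(act)[3L]
  Y <- matrix(act, nrow = n)                 # n x (regions * timepoints)
  xc <- x - mean(x)
  sxx <- sum(xc^2)
  ym <- colMeans(Y)
  b <- as.numeric(crossprod(xc, Y)) / sxx
  a0 <- ym - b * mean(x)
  # residual sum of squares without forming the residual matrix twice
  res <- Y - outer(rep(1, n), ym) - outer(xc, b)
  df <- n - 2L
  sigma2 <- colSums(res^2) / df
  se <- sqrt(sigma2 / sxx)
  tval <- b / se
  pval <- 2 * stats::pt(-abs(tval), df)
  exact <- se == 0                           # zero residual variance
  pval[exact & b != 0] <- 0                  # perfect nonzero fit
  pval[exact & b == 0] <- 1                  # constant series: no evidence
  tval[exact & b == 0] <- 0
  shape <- function(v) matrix(v, nr, nt)
  p <- shape(pval)
  structure(
    list(beta = shape(b), intercept = shape(a0), t = shape(tval), p = p,
         fdr_mask = fdr_correct(p, q), q = q, df = df, n = n),
    class = "mass_ols"
  )
}

#' @export
print.mass_ols <- function(x, ...) {
  cat(sprintf("Mass-univariate OLS: %d regions x %d timepoints, %d trials\n",
              nrow(x$beta), ncol(x$beta), x$n))
  cat(sprintf("  %d of %d tests significant at FDR q = %g\n",
              sum(x$fdr_mask), length(x$fdr_mask), x$q))
  invisible(x)
}

#' @export
plot.mass_ols <- function(x, region = 1L, ...) {
  tvec <- x$t[region, ]
  graphics::plot(seq_along(tvec), tvec, type = "l", xlab = "timepoint",
                 ylab = "t", main = sprintf("region %d", region))
  sig <- which(x$fdr_mask[region, ])
  if (length(sig)) {
    graphics::points(sig, tvec[sig], pch = 16, col = "darkgreen")
  }
  graphics::abline(h = 0, lty = 2, col = "grey")
  invisible(x)
}

#' Benjamini-Hochberg false discovery rate mask
#'
#' Step-up FDR control over the flattened array of p values: a test is
#' retained when its BH-adjusted p value is at most `q`.
#'
#' @param p_values numeric vector, matrix or array of p values in \[0, 1\].
#' @param q FDR level.
#' @return logical object of the same shape; `TRUE` marks rejections.
#' @examples
#' fdr_correct(c(0.001, 0.01, 0.02, 0.5), q = 0.05)
#' @export
fdr_correct <- function(p_values, q = 0.05) {
  if (length(p_values) == 0L) return(logical(0))
  if (any(p_values < 0 | p_values > 1, na.rm = TRUE)) {
    stop("p values must lie in [0, 1]")
  }
  mask <- stats::p.adjust(as.vector(p_values), method = "BH") <= q
  if (!is.null(dim(p_values))) dim(mask) <- dim(p_values)
  mask
}
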