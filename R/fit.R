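# Per-participant likelihoods, global optimization, BIC, and the
# three-model comparison.

.model_names <- c("aif", "mf", "mb")

.ll_engine <- function(model_name, params, data, config, collect = FALSE) {
  switch(model_name,
         aif = .aif_engine(params, config, data = data, collect = collect),
         mf  = .mf_engine(params, config, data = data, collect = collect),
         mb  = .mb_engine(params, config, data = data, collect = collect),
         stop("unknown model: ", model_name))
}

#' Teacher-forced choice log likelihood
#'
#' Steps a model through the realized observations and rewards of a
#' session (teacher forcing) and sums the log probability it assigned to
#' every free choice. Forced Stay choices on no-ask trials are excluded
#' from the sum; both stages of every other trial contribute. Recorded
#' actions assigned (numerically) zero probability contribute `log(1e-16)`
#' and are counted in the `n_flagged` attribute.
#'
#' @param model_name `"aif"`, `"mf"` or `"mb"`.
#' @param params named parameters of the model (see [fit_bandit()] for the
#'   free-parameter lists).
#' @param data a `"bandit_session"`.
#' @param config the [task_config()]; defaults to the one attached to
#'   `data`.
#' @return log likelihood in nats, with attributes `n` (number of modeled
#'   choices) and `n_flagged`.
#' @export
choice_log_likelihood <- function(model_name, params, data,
                                  config = attr(data, "config")) {
  if (is.null(config)) config <- task_config()
  eng <- .ll_engine(match.arg(model_name, .model_names), params, data, config)
  structure(eng$log_likelihood, n = eng$n, n_flagged = eng$n_flagged)
}

#' Bayesian information criterion
#'
#' `BIC = k * ln(n) - 2 * logLik`; lower is better.
#'
#' @param log_likelihood maximized log likelihood in nats.
#' @param k number of free parameters.
#' @param n number of modeled choices.
#' @return the BIC value.
#' @export
bic <- function(log_likelihood, k, n) {
  if (n < 1) stop("n must be >= 1")
  if (k < 0) stop("k must be >= 0")
  k * log(n) - 2 * as.numeric(log_likelihood)
}

#' Default parameter bounds for fitting
#'
#' @param model_name `"aif"`, `"mf"` or `"mb"`.
#' @return matrix with one row per free parameter and columns `lower`,
#'   `upper`.
#' @export
default_bounds <- function(model_name = c("aif", "mf", "mb")) {
  model_name <- match.arg(model_name)
  b <- switch(model_name,
    aif = rbind(AL = c(0, 10), AI = c(0, 10), EX = c(0, 10),
                prior = c(1e-3, 10), alpha = c(0, 1)),
    mf = rbind(alpha_mf = c(0, 1), gamma_mf = c(1e-3, 10)),
    mb = rbind(alpha_mb = c(0, 1), gamma_mb = c(1e-3, 10),
               prior_mb = c(0, 12))
  )
  colnames(b) <- c("lower", "upper")
  b
}

# Global maximization: a random exploration phase over the box, then
# guided iterations of bound-clamped Nelder-Mead refinement started from
# the incumbent (restarted with a jittered simplex whenever it converges
# before the evaluation budget is spent). Every probed point is recorded;
# the returned optimum dominates all probes.
.global_opt <- function(fn, bounds, n_random, n_iter, seed) {
  if (n_random < 1 || n_iter < 0) {
    stop("invalid budget: need at least one random probe")
  }
  set.seed(seed)
  k <- nrow(bounds)
  lo <- bounds[, 1L]; hi <- bounds[, 2L]
  span <- hi - lo
  total <- n_random + n_iter
  # The search runs in unit coordinates u with x = lo + span * u^2: the
  # square map gives the local search finer resolution at small parameter
  # values, where the likelihood of scale-like parameters curves most.
  to_x <- function(u) lo + span * u^2
  probes <- matrix(NA_real_, total, k, dimnames = list(NULL, rownames(bounds)))
  u_best <- NULL
  score <- rep(NA_real_, total)
  used <- 0L
  record <- function(x, v) {
    used <<- used + 1L
    probes[used, ] <<- x
    score[used] <<- v
  }
  best_i <- function() which.max(score[seq_len(used)])
  u_tab <- matrix(stats::runif(n_random * k), n_random, k)
  for (i in seq_len(n_random)) {
    x <- to_x(u_tab[i, ])
    record(x, fn(x))
  }
  v_best <- max(score[seq_len(n_random)])
  u_best <- u_tab[which.max(score[seq_len(n_random)]), ]
  first_restart <- TRUE
  while (used < total) {
    u0 <- if (first_restart) u_best else {
      .clip(u_best + stats::rnorm(k, 0, 0.05), 0, 1)
    }
    first_restart <- FALSE
    pen_fn <- function(u) {
      if (used >= total) stop("budget exhausted")
      uc <- .clip(u, 0, 1)
      x <- to_x(uc)
      v <- fn(x)
      record(x, v)
      if (v > v_best) {
        v_best <<- v
        u_best <<- uc
      }
      v - sum((u - uc)^2)  # penalty for leaving the unit box
    }
    try(stats::optim(u0, pen_fn, method = "Nelder-Mead",
                     control = list(fnscale = -1, maxit = 10 * total)),
        silent = TRUE)
  }
  b <- best_i()
  list(par = probes[b, ], value = score[b],
       trace = data.frame(probes[seq_len(used), , drop = FALSE],
                          value = score[seq_len(used)]))
}

#' Fit a decision model to a behavioral session
#'
#' Maximizes the teacher-forced choice log likelihood of one participant's
#' session by global optimization (random exploration followed by guided
#' local refinement) within box bounds, and reports the Bayesian
#' information criterion. Free parameters: active inference `"aif"` fits
#' `AL`, `AI`, `EX`, `prior`, `alpha` (k = 5; the policy precision `gamma`
#' is fixed at 1); model-free `"mf"` fits `alpha_mf`, `gamma_mf` (k = 2);
#' model-based `"mb"` fits `alpha_mb`, `gamma_mb`, `prior_mb` (k = 3).
#'
#' @param data a `"bandit_session"`.
#' @param model `"aif"`, `"mf"` or `"mb"`.
#' @param budget integer vector `c(n_random, n_iter)`: random probes, then
#'   guided iterations.
#' @param seed integer seed; fits are reproducible.
#' @param bounds parameter bounds matrix as from [default_bounds()].
#' @param config the [task_config()]; defaults to the one attached to
#'   `data`.
#' @return an object of class `"bandit_fit"` with components
#'   `model_name`, `params`, `log_likelihood`, `k`, `n`, `bic`,
#'   `optimizer_trace`, `n_flagged`, `seed`, `data`, `config`. Methods:
#'   `print`, `summary`, `coef`, `logLik`, `predict`, `simulate`,
#'   `residuals`, `plot`.
#' @examples
#' s <- run_rl_agent("mf", list(alpha_mf = 0.3, gamma_mf = 2),
#'                   task_config(n_trials = 40), seed = 1)
#' fit <- fit_bandit(s, "mf", budget = c(25, 25), seed = 1)
#' coef(fit)
#' @export
fit_bandit <- function(data, model = c("aif", "mf", "mb"),
                       budget = c(1000, 1000), seed = 1L,
                       bounds = default_bounds(model),
                       config = attr(data, "config")) {
  model <- match.arg(model)
  if (is.null(config)) config <- task_config()
  if (length(budget) != 2L || any(budget < 0) || sum(budget) < 1) {
    stop("invalid budget: supply c(n_random, n_iter) with at least one probe")
  }
  fn <- function(theta) {
    as.numeric(choice_log_likelihood(model, as.list(theta), data, config))
  }
  opt <- .global_opt(fn, bounds, budget[1L], budget[2L], seed)
  eng <- .ll_engine(model, as.list(opt$par), data, config)
  structure(
    list(model_name = model, params = as.list(opt$par),
         log_likelihood = eng$log_likelihood, k = nrow(bounds), n = eng$n,
         bic = bic(eng$log_likelihood, nrow(bounds), eng$n),
         optimizer_trace = opt$trace, n_flagged = eng$n_flagged,
         seed = seed, budget = budget, bounds = bounds,
         data = data, config = config),
    class = "bandit_fit"
  )
}

#' @export
print.bandit_fit <- function(x, ...) {
  cat(sprintf("Fitted %s model (%d free parameters, %d choices)\n",
              x$model_name, x$k, x$n))
  cat("  ", paste(sprintf("%s = %.3f", names(x$params),
                          unlist(x$params)), collapse = ", "), "\n")
  cat(sprintf("  logLik = %.2f, BIC = %.2f\n", x$log_likelihood, x$bic))
  if (x$n_flagged > 0) {
    cat(sprintf("  note: %d recorded choice(s) hit the probability floor\n",
                x$n_flagged))
  }
  invisible(x)
}

#' @export
summary.bandit_fit <- function(object, ...) {
  out <- list(model_name = object$model_name,
              params = unlist(object$params),
              log_likelihood = object$log_likelihood,
              k = object$k, n = object$n, bic = object$bic,
              n_flagged = object$n_flagged,
              n_probes = nrow(object$optimizer_trace))
  class(out) <- "summary.bandit_fit"
  out
}

#' @export
print.summary.bandit_fit <- function(x, ...) {
  cat(sprintf("Model: %s   logLik %.3f   k %d   n %d   BIC %.3f\n",
              x$model_name, x$log_likelihood, x$k, x$n, x$bic))
  print(round(x$params, 4))
  cat(sprintf("%d optimizer probes, %d floored choice(s)\n",
              x$n_probes, x$n_flagged))
  invisible(x)
}

#' @export
coef.bandit_fit <- function(object, ...) unlist(object$params)

#' @export
logLik.bandit_fit <- function(object, ...) {
  structure(object$log_likelihood, df = object$k, nobs = object$n,
            class = "logLik")
}

#' Per-trial choice probabilities of a fitted model
#'
#' Replays the fitted model through a session (the fitted one by default)
#' and returns the probability assigned to each available and to each
#' observed choice.
#'
#' @param object a `"bandit_fit"`.
#' @param newdata optional `"bandit_session"` to replay instead of the
#'   fitted data.
#' @param ... unused.
#' @return data frame with one row per trial: `p_cue`, `p_risky`, and the
#'   probabilities of the recorded first/second actions (`p_obs_first` is
#'   `NA` on forced trials).
#' @export
predict.bandit_fit <- function(object, newdata = NULL, ...) {
  data <- if (is.null(newdata)) object$data else newdata
  eng <- .ll_engine(object$model_name, object$params, data, object$config,
                    collect = TRUE)
  tr <- eng$trials
  data.frame(trial = tr$trial, can_ask = tr$can_ask,
             p_cue = tr$p_cue, p_risky = tr$p_risky,
             p_obs_first = ifelse(tr$can_ask,
                                  ifelse(tr$first_action == "Cue",
                                         tr$p_cue, 1 - tr$p_cue), NA_real_),
             p_obs_second = ifelse(tr$second_action == "Risky",
                                   tr$p_risky, 1 - tr$p_risky))
}

#' @export
residuals.bandit_fit <- function(object, type = c("response", "deviance"),
                                 ...) {
  type <- match.arg(type)
  pr <- stats::predict(object)
  p <- c(pr$p_obs_first[pr$can_ask], pr$p_obs_second)
  if (type == "response") 1 - p else sqrt(-2 * log(pmax(p, .LOG_FLOOR)))
}

#' @export
simulate.bandit_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max, nsim)
  lapply(seq_len(nsim), function(i) {
    if (object$model_name == "aif") {
      trace_to_session(run_agent(object$params, object$config,
                                 seed = seeds[i],
                                 participant_id = paste0("sim", i)))
    } else {
      run_rl_agent(object$model_name, object$params, object$config,
                   seed = seeds[i], participant_id = paste0("sim", i))
    }
  })
}

#' @export
plot.bandit_fit <- function(x, ...) {
  pr <- stats::predict(x)
  graphics::plot(pr$trial, pr$p_obs_second, type = "h", ylim = c(0, 1),
                 xlab = "trial", ylab = "P(observed choice)",
                 main = sprintf("%s model fit", x$model_name))
  ok <- pr$can_ask
  graphics::points(pr$trial[ok], pr$p_obs_first[ok], pch = 1, col = "blue")
  graphics::abline(h = 0.5, lty = 2, col = "grey")
  graphics::legend("bottomright", legend = c("second choice", "first choice"),
                   col = c("black", "blue"), lty = c(1, NA),
                   pch = c(NA, 1), bty = "n")
  invisible(x)
}

#' Fit and compare all candidate models across a cohort
#'
#' Fits the active inference, model-free and model-based models to every
#' participant with a shared budget and seed policy, and tabulates
#' log likelihoods and BICs.
#'
#' @param cohort a `"bandit_cohort"` from [generate_cohort()], or a list of
#'   `"bandit_session"` objects.
#' @param models subset of `c("aif", "mf", "mb")`.
#' @param budget optimizer budget per fit, as in [fit_bandit()].
#' @param seed integer; participant seeds are derived from it.
#' @param config task configuration; defaults to each session's own.
#' @return an object of class `"bandit_comparison"`: a data frame with one
#'   row per participant x model (`participant`, `model`, `log_likelihood`,
#'   `k`, `n`, `bic`), with the per-model mean BIC in
#'   `attr(, "mean_bic")` and fitted parameter tables in
#'   `attr(, "params")`.
#' @export
compare_bandit_models <- function(cohort, models = c("aif", "mf", "mb"),
                                  budget = c(100, 100), seed = 1L,
                                  config = NULL) {
  sessions <- if (inherits(cohort, "bandit_cohort")) cohort$sessions else cohort
  models <- match.arg(models, several.ok = TRUE)
  rows <- list(); params <- list()
  for (i in seq_along(sessions)) {
    s <- sessions[[i]]
    pid <- s$participant_id[1L]
    cfg <- if (is.null(config)) attr(s, "config") else config
    # fit seeds derive from the participant id, so results do not depend
    # on the order sessions are supplied in
    pid_seed <- seed + sum(utf8ToInt(pid)) %% 100000L
    for (m in models) {
      f <- fit_bandit(s, m, budget = budget, seed = pid_seed, config = cfg)
      rows[[length(rows) + 1L]] <-
        data.frame(participant = pid, model = m,
                   log_likelihood = f$log_likelihood, k = f$k, n = f$n,
                   bic = f$bic, stringsAsFactors = FALSE)
      params[[paste(pid, m, sep = ".")]] <- unlist(f$params)
    }
  }
  tab <- do.call(rbind, rows)
  mean_bic <- tapply(tab$bic, tab$model, mean)
  structure(tab, class = c("bandit_comparison", "data.frame"),
            mean_bic = mean_bic, params = params)
}

#' @export
print.bandit_comparison <- function(x, ...) {
  cat("Model comparison across", length(unique(x$participant)),
      "participant(s)\n")
  mb <- attr(x, "mean_bic")
  cat("Mean BIC per model (lower is better):\n")
  print(round(mb[order(mb)], 2))
  best <- vapply(split(as.data.frame(x), x$participant),
                 function(d) d$model[which.min(d$bic)], character(1))
  cat("Best model per participant:\n")
  print(table(best))
  invisible(x)
}
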