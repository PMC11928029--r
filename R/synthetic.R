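# Synthetic stand-ins for the study's behavioral and neural data: cohorts
# of simulated participants with known parameters, and neural epochs with
# planted linear regressor effects.

.default_ranges <- function(generator) {
  switch(generator,
    aif = list(AL = c(0.25, 2), AI = c(0.25, 2), EX = c(0.5, 4),
               prior = c(0.25, 2), alpha = c(0.1, 0.9)),
    mf = list(alpha_mf = c(0.1, 0.9), gamma_mf = c(0.5, 3)),
    mb = list(alpha_mb = c(0.1, 0.9), gamma_mb = c(0.5, 3),
              prior_mb = c(3, 9))
  )
}

#' Specification of a synthetic cohort
#'
#' Describes how to generate a cohort of simulated participants: the
#' generating model, per-parameter uniform sampling ranges, the task, and
#' a master seed. Defaults mirror the study's cohort size (25 participants,
#' 120 trials each); the parameter ranges span the qualitatively distinct
#' behavioral regimes of each model, produce human-like choice
#' stochasticity at the model's fixed policy precision (see the package
#' vignette for the effective-units reasoning), and lie inside the fitting
#' bounds.
#'
#' @param n_participants cohort size.
#' @param generator `"aif"`, `"mf"` or `"mb"`.
#' @param parameter_ranges named list of `c(lower, upper)` sampling ranges;
#'   defaults depend on the generator.
#' @param task a [task_config()].
#' @param master_seed integer seed governing both parameter draws and
#'   session simulation.
#' @return an object of class `"cohort_spec"`.
#' @export
cohort_spec <- function(n_participants = 25L,
                        generator = c("aif", "mf", "mb"),
                        parameter_ranges = NULL,
                        task = task_config(),
                        master_seed = 1L) {
  generator <- match.arg(generator)
  if (n_participants < 1L) stop("n_participants must be >= 1")
  ranges <- if (is.null(parameter_ranges)) {
    .default_ranges(generator)
  } else parameter_ranges
  bounds <- default_bounds(generator)
  for (nm in names(ranges)) {
    rg <- ranges[[nm]]
    if (!nm %in% rownames(bounds)) stop("unknown parameter in ranges: ", nm)
    if (rg[1L] > rg[2L] || rg[1L] < bounds[nm, 1L] || rg[2L] > bounds[nm, 2L]) {
      stop("sampling range for ", nm, " must lie within the fitting bounds")
    }
  }
  structure(list(n_participants = as.integer(n_participants),
                 generator = generator, parameter_ranges = ranges,
                 task = task, master_seed = as.integer(master_seed)),
            class = "cohort_spec")
}

#' Generate a synthetic cohort with known ground truth
#'
#' Draws each participant's parameters uniformly from the spec's ranges,
#' simulates a full session with the generating model, and records the
#' ground-truth parameter table, so parameter- and model-recovery analyses
#' need no external input.
#'
#' @param spec a [cohort_spec()].
#' @return an object of class `"bandit_cohort"`: a list with `sessions`
#'   (list of `"bandit_session"`), `truth` (data frame of generating
#'   parameters per participant), and `spec`.
#' @examples
#' coh <- generate_cohort(cohort_spec(n_participants = 2,
#'                                    task = task_config(n_trials = 20)))
#' coh$truth
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  set.seed(spec$master_seed)
  n <- spec$n_participants
  ranges <- spec$parameter_ranges
  par_tab <- vapply(names(ranges), function(nm) {
    stats::runif(n, ranges[[nm]][1L], ranges[[nm]][2L])
  }, numeric(n))
  par_tab <- matrix(par_tab, nrow = n,
                    dimnames = list(NULL, names(ranges)))
  sim_seeds <- sample.int(2147483646L, n)
  sessions <- vector("list", n)
  for (i in seq_len(n)) {
    pid <- sprintf("%s_%02d", spec$generator, i)
    params <- as.list(par_tab[i, ])
    sessions[[i]] <- if (spec$generator == "aif") {
      trace_to_session(run_agent(params, spec$task, seed = sim_seeds[i],
                                 participant_id = pid))
    } else {
      run_rl_agent(spec$generator, params, spec$task, seed = sim_seeds[i],
                   participant_id = pid)
    }
  }
  truth <- data.frame(participant = vapply(sessions, function(s)
    s$participant_id[1L], character(1)), par_tab,
    seed = sim_seeds, stringsAsFactors = FALSE)
  structure(list(sessions = sessions, truth = truth, spec = spec),
            class = "bandit_cohort")
}

#' @export
print.bandit_cohort <- function(x, ...) {
  cat(sprintf("Synthetic cohort: %d participants x %d trials, generator '%s'\n",
              length(x$sessions), x$spec$task$n_trials, x$spec$generator))
  cat("Ground-truth parameters:\n")
  print(utils::head(x$truth, 5))
  if (nrow(x$truth) > 5) cat("...", nrow(x$truth) - 5, "more\n")
  invisible(x)
}

#' Write a cohort's sessions as CSV logs
#'
#' One CSV per participant plus a `ground_truth.csv` table.
#'
#' @param cohort a `"bandit_cohort"`.
#' @param dir output directory (created if needed).
#' @return the directory, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  for (s in cohort$sessions) {
    write_session(s, file.path(dir, paste0(s$participant_id[1L], ".csv")))
  }
  utils::write.csv(cohort$truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(dir)
}

#' Generate neural epochs with a planted regressor effect
#'
#' Emulates source-space trial epochs as a trials x regions x timepoints
#' array: i.i.d. Gaussian noise (optionally AR(1)-correlated over time)
#' plus, inside one region's effect window, `beta_true` times the z-scored
#' regressor. The ground-truth effect map is stored with the epochs so
#' recovery and calibration of the regression machinery can be verified.
#'
#' @param regressor per-trial regressor values (z-scored internally before
#'   planting, so `beta_true` has a fixed scale).
#' @param beta_true effect amplitude per unit (z-scored) regressor.
#' @param noise_sd Gaussian noise standard deviation (>= 0).
#' @param n_regions,n_timepoints array dimensions.
#' @param effect_region region index carrying the effect.
#' @param effect_window integer vector of timepoints carrying the effect;
#'   defaults to the middle fifth of the epoch.
#' @param sampling_rate in Hz, stored as metadata (default 250).
#' @param ar1 optional AR(1) coefficient for temporally correlated noise.
#' @param seed integer seed.
#' @param region_labels character labels for the regions.
#' @return an object of class `"neural_epochs"`: a list with `activity`
#'   (trials x regions x timepoints), `sampling_rate`, `region_labels` and
#'   the ground `truth`.
#' @export
generate_neural_epochs <- function(regressor, beta_true = 0.5, noise_sd = 1,
                                   n_regions = 8L, n_timepoints = 100L,
                                   effect_region = 1L, effect_window = NULL,
                                   sampling_rate = 250, ar1 = 0,
                                   seed = NULL,
                                   region_labels = paste0("region_",
                                                          seq_len(n_regions))) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  n <- length(regressor)
  if (stats::var(regressor) == 0) stop("regressor has zero variance")
  z <- as.numeric(scale(regressor))
  if (is.null(effect_window)) {
    effect_window <- seq(floor(0.4 * n_timepoints) + 1L,
                         ceiling(0.6 * n_timepoints))
  }
  if (!is.null(seed)) set.seed(seed)
  noise <- stats::rnorm(n * n_regions * n_timepoints, sd = noise_sd)
  act <- array(noise, dim = c(n, n_regions, n_timepoints))
  if (ar1 != 0) {
    for (i in seq_len(n)) for (j in seq_len(n_regions)) {
      act[i, j, ] <- as.numeric(stats::filter(act[i, j, ], ar1,
                                              method = "recursive"))
    }
  }
  act[, effect_region, effect_window] <-
    act[, effect_region, effect_window] + beta_true * z
  structure(
    list(activity = act, sampling_rate = sampling_rate,
         region_labels = region_labels,
         truth = list(beta_true = beta_true, effect_region = effect_region,
                      effect_window = effect_window, noise_sd = noise_sd,
                      regressor_z = z)),
    class = "neural_epochs"
  )
}

#' @export
print.neural_epochs <- function(x, ...) {
  d <- dim(x$activity)
  cat(sprintf("Neural epochs: %d trials x %d regions x %d timepoints (%g Hz)\n",
              d[1L], d[2L], d[3L], x$sampling_rate))
  cat(sprintf("Planted effect: beta = %g in %s, %d timepoints\n",
              x$truth$beta_true, x$region_labels[x$truth$effect_region],
              length(x$truth$effect_window)))
  invisible(x)
}
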