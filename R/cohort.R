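#' Simulate one response from an observer
#'
#' Draws the full generative process of the observer on a trial: latent
#' internal measurements (factor S cue measurement, factor P prior
#' perturbation), a lapse coin, the decision rule's target choice, and
#' motor noise.
#'
#' @inheritParams target_choice_density
#' @return A response position (scalar).
#' @export
simulate_response <- function(spec, params, trial, config = priorcue_config(),
                              priors = NULL) {
  spec <- parse_observer(spec)
  prior <- trial_prior(trial, config, priors)
  sl <- subj_lik_sd(params, trial)
  ss <- cue_est_sd(spec, params, trial, config)
  eta <- if (spec$P) session_par(params, trial, "weber_prior") else 0
  np <- n_p_latents(spec, prior)
  pr <- if (np > 0L) perturb_prior(prior, eta, stats::rnorm(np)) else prior
  cue_m <- if (spec$S && ss > 0) stats::rnorm(1, trial$cue_x, ss) else trial$cue_x
  lam <- if (spec$L) session_par(params, trial, "lapse") else 0
  target <- if (lam > 0 && stats::runif(1) < lam) {
    gm_sample(1, pr)
  } else {
    draw_choice(spec, params, pr, cue_m, sqrt(sl^2 + ss^2), config, trial)
  }
  stats::rnorm(1, target, params[["motor_sd"]])
}

# One draw from the decision rule's target-choice distribution.
draw_choice <- function(spec, params, prior, cue_m, lik_sd_eff, config, trial) {
  post <- posterior_update(prior, cue_m, lik_sd_eff)$base
  post <- apply_ga(post, spec$ga)
  switch(spec$decision,
    BDT = optimal_target(post, config$loss),
    PPM = gm_sample(1, post),
    SPK = {
      if (length(post$weights) == 1L)
        stats::rnorm(1, post$means, post$sds / sqrt(session_par(params, trial, "kappa")))
      else dens_sample(1, power_density(post, session_par(params, trial, "kappa")))
    },
    PSA = {
      k <- session_par(params, trial, "psa_k")
      if (length(post$weights) == 1L) return(stats::rnorm(1, post$means, post$sds / sqrt(k)))
      # real-valued k: randomize between adjacent integers with the
      # interpolation weight (matches the interpolated density exactly)
      k0 <- floor(k)
      ki <- if (stats::runif(1) < k - k0) k0 + 1 else k0
      mean(gm_sample(ki, post))
    })
}

#' Simulate a complete synthetic subject
#'
#' A two-session dataset (Gaussian training session followed by the
#' group's test session) with responses generated by the given observer
#' model, reproducible from the seed.
#'
#' @param group Test-session prior class: `"gaussian"`, `"unimodal"` or
#'   `"bimodal"`.
#' @param spec Observer model generating the responses.
#' @param theta Named parameter vector on the natural scale.
#' @param seed Integer seed; the whole dataset is a deterministic function
#'   of it.
#' @param config A [priorcue_config()].
#' @param subject_id Identifier stored on the result.
#' @param repetitions Trials per condition.
#' @return Object of class `"subject_sim"`: list with `subject_id`,
#'   `group`, `spec`, `theta`, `seed`, `data` (trial records with
#'   `response_x` filled).
#' @export
simulate_subject <- function(group, spec, theta, seed,
                             config = priorcue_config(), subject_id = "S01",
                             repetitions = config$repetitions) {
  spec <- parse_observer(spec)
  set.seed(seed)
  sessions <- list(
    list(session = "training", prior_class = "gaussian"),
    list(session = "test", prior_class = group))
  data <- do.call(rbind, lapply(sessions, function(se) {
    plan <- build_session_plan(se$session, se$prior_class, repetitions)
    priors <- session_priors(se$prior_class, config)
    trials <- sample_session(plan, priors, config)
    trials$response_x <- vapply(seq_len(nrow(trials)), function(i)
      simulate_response(spec, theta, trials[i, ], config, priors), numeric(1))
    trials
  }))
  rownames(data) <- NULL
  data$subject <- subject_id
  structure(list(subject_id = subject_id, group = group, spec = spec,
                 theta = theta, seed = seed, data = data),
            class = "subject_sim")
}

#' Simulate a group of subjects
#'
#' Independent subjects whose parameter vectors are drawn around a
#' population mean: log-normal scatter for strictly positive parameters,
#' with hard truncation to each parameter's support (lapse rates to (0, 1),
#' prior-noise to (0, 4], decision powers to at least 1).
#'
#' @param n_subjects Number of subjects.
#' @param spec Generating observer model.
#' @param theta_population Named list with `mean` (natural-scale vector as
#'   [default_params()]) and `sdlog` (log-scale scatter, scalar or named).
#' @param seed Integer seed.
#' @param group Test-session prior class shared by the group.
#' @param config A [priorcue_config()].
#' @param repetitions Trials per condition.
#' @return List of `subject_sim` objects.
#' @export
simulate_group <- function(n_subjects, spec,
                           theta_population = list(mean = default_params(spec),
                                                   sdlog = 0.1),
                           seed = 1L, group = "gaussian",
                           config = priorcue_config(),
                           repetitions = config$repetitions) {
  spec <- parse_observer(spec)
  set.seed(seed)
  mu <- theta_population$mean[param_names(spec)]
  sdlog <- theta_population$sdlog
  if (length(sdlog) == 1L) sdlog <- stats::setNames(rep(sdlog, length(mu)), names(mu))
  thetas <- lapply(seq_len(n_subjects), function(i) {
    th <- mu * exp(stats::rnorm(length(mu), 0, sdlog[names(mu)]))
    th <- clamp_params(th)
    th
  })
  seeds <- sample.int(.Machine$integer.max %/% 2L, n_subjects)
  lapply(seq_len(n_subjects), function(i)
    simulate_subject(group, spec, thetas[[i]], seeds[i], config,
                     subject_id = sprintf("S%02d", i), repetitions = repetitions))
}

clamp_params <- function(th) {
  for (nm in names(th)) {
    if (grepl("^lapse", nm)) th[nm] <- min(max(th[nm], 1e-4), 0.5)
    if (grepl("^weber", nm)) th[nm] <- min(max(th[nm], 1e-4), 4)
    if (grepl("^(kappa|psa_k)", nm)) th[nm] <- max(th[nm], 1)
    if (grepl("sd", nm)) th[nm] <- min(max(th[nm], 1e-4), 0.9)
  }
  th
}

#' Parameter- and model-recovery experiment
#'
#' Simulates a group from a generating observer, fits every candidate
#' model to every subject by MCMC, and summarizes DIC-based model selection
#' (random-effects BMS) together with parameter-recovery coverage of the
#' generating values.
#'
#' @param generating_spec Observer generating the data.
#' @param candidate_specs List of candidate models to fit.
#' @param n_subjects Number of simulated subjects.
#' @param budget MCMC budget, see [fit_observer()].
#' @param seed Integer seed.
#' @param group Test-session prior class.
#' @param config A [priorcue_config()].
#' @param theta_population Passed to [simulate_group()].
#' @param repetitions Trials per condition.
#' @return List with `dic` (subjects x models matrix), `bms`, `fits`,
#'   `coverage` (per subject, generating parameters inside central 95%
#'   posterior intervals under the generating model), `failures`.
#' @export
recovery_experiment <- function(generating_spec, candidate_specs, n_subjects,
                                budget = list(n_chains = 3L, burn_in = 100L,
                                              n_samples = 300L),
                                seed = 1L, group = "gaussian",
                                config = priorcue_config(),
                                theta_population = NULL,
                                repetitions = config$repetitions) {
  generating_spec <- parse_observer(generating_spec)
  candidate_specs <- lapply(candidate_specs, parse_observer)
  if (is.null(theta_population))
    theta_population <- list(mean = default_params(generating_spec), sdlog = 0.1)
  subs <- simulate_group(n_subjects, generating_spec, theta_population, seed,
                         group, config, repetitions)
  ids <- vapply(candidate_specs, function(s) s$id, character(1))
  dic <- matrix(NA_real_, n_subjects, length(candidate_specs),
                dimnames = list(vapply(subs, function(s) s$subject_id, character(1)), ids))
  fits <- list(); failures <- list()
  coverage <- vector("list", n_subjects)
  set.seed(seed + 1L)
  fit_seeds <- matrix(sample.int(.Machine$integer.max %/% 2L,
                                 n_subjects * length(candidate_specs)),
                      n_subjects, length(candidate_specs))
  for (i in seq_len(n_subjects)) {
    for (j in seq_along(candidate_specs)) {
      fit <- try(fit_observer(candidate_specs[[j]], subs[[i]]$data, config,
                              seed = fit_seeds[i, j], budget = budget),
                 silent = TRUE)
      if (inherits(fit, "try-error")) {
        failures[[length(failures) + 1L]] <-
          list(subject = i, model = ids[j], error = as.character(fit))
        next
      }
      dic[i, j] <- fit$dic
      fits[[paste(i, ids[j], sep = ":")]] <- fit
      if (ids[j] == generating_spec$id)
        coverage[[i]] <- covered_by_interval(fit, subs[[i]]$theta)
    }
  }
  bms <- if (all(is.finite(dic)))
    bms_fit(-dic / 2, seed = seed + 2L) else NULL
  list(subjects = subs, dic = dic, bms = bms, fits = fits,
       coverage = coverage, failures = failures)
}

covered_by_interval <- function(fit, theta, level = 0.95) {
  a <- (1 - level) / 2
  sam <- fit$samples
  nm <- intersect(colnames(sam), names(theta))
  vapply(nm, function(p) {
    qs <- stats::quantile(sam[, p], c(a, 1 - a), names = FALSE)
    theta[[p]] >= qs[1] && theta[[p]] <= qs[2]
  }, logical(1))
}
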