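#' The basic factorial model set
#'
#' Decision rules BDT/SPK/PPM crossed with the optional S, P and L
#' factors: 24 observer models.
#'
#' @return Character vector of canonical model strings.
#' @export
basic_model_set <- function() {
  grid <- expand.grid(decision = c("BDT", "SPK", "PPM"),
                      S = c(FALSE, TRUE), P = c(FALSE, TRUE), L = c(FALSE, TRUE),
                      stringsAsFactors = FALSE)
  vapply(seq_len(nrow(grid)), function(i)
    observer_spec(grid$decision[i], S = grid$S[i], P = grid$P[i], L = grid$L[i])$id,
    character(1))
}

#' Distinct models of the extended decision-making comparison
#'
#' Enumerates decision rule {BDT, SPK, PPM, PSA} x Gaussian approximation
#' {none, MV, LA} x lapse {off, on} (24 combinations) and merges
#' combinations whose target-choice distribution families coincide,
#' verified by response-density comparison on a battery of non-Gaussian
#' trials over a shared grid of decision-power values.
#'
#' Deterministic (BDT-type) observers are compared on the decision
#' functional of the task's hit-window loss in its narrow-loss limit, the
#' posterior mode: the Laplace approximation preserves the mode by
#' construction, so the loss-smoothing device used for numerical mode
#' finding is not allowed to separate families that prescribe the same
#' action. On a single-Gaussian (MV or LA) approximated posterior the
#' stochastic-posterior and sample-averaging rules generate the identical
#' Gaussian family, which produces the remaining merges.
#'
#' @param config A [priorcue_config()].
#' @param powers Shared decision-power grid used in the comparison.
#' @param lapse Lapse rate applied to the lapse combinations.
#' @param motor_sd Motor sd used in the comparison.
#' @param tol Relative sup-norm tolerance for density identity.
#' @return List with `combos` (all 24 strings), `classes` (list of merged
#'   groups), `merged` (data frame of merged pairs), `n_distinct`.
#' @export
extended_model_set <- function(config = priorcue_config(),
                               powers = c(1, 2, 4), lapse = 0.15,
                               motor_sd = 0.01, tol = 1e-6) {
  grid <- expand.grid(decision = c("BDT", "SPK", "PPM", "PSA"),
                      ga = c("none", "MV", "LA"), L = c(FALSE, TRUE),
                      stringsAsFactors = FALSE)
  combos <- lapply(seq_len(nrow(grid)), function(i)
    observer_spec(grid$decision[i], ga = grid$ga[i], L = grid$L[i]))
  ids <- vapply(combos, function(s) s$id, character(1))

  battery <- equivalence_battery(config)
  rgrid <- seq(-0.45, 0.45, by = 2e-3)

  sig <- lapply(combos, function(sp)
    combo_signature(sp, battery, rgrid, powers, lapse, motor_sd))

  n <- length(combos)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  merged <- NULL
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (nrow(sig[[i]]) != nrow(sig[[j]])) next
    if (grid$L[i] != grid$L[j]) next
    dmax <- max(abs(sig[[i]] - sig[[j]]))
    if (dmax <= tol * max(sig[[i]])) {
      ri <- find(i); rj <- find(j)
      if (ri != rj) parent[max(ri, rj)] <- min(ri, rj)
      merged <- rbind(merged, data.frame(a = ids[i], b = ids[j],
                                         max_diff = dmax,
                                         stringsAsFactors = FALSE))
    }
  }
  roots <- vapply(seq_len(n), find, integer(1))
  classes <- split(ids, roots)
  names(classes) <- vapply(classes, `[`, character(1), 1)
  list(combos = ids, classes = classes, merged = merged,
       n_distinct = length(classes))
}

# Non-Gaussian posteriors probing the decision rules: unimodal and bimodal
# session priors with cues at informative offsets, at two subjective
# likelihood sds.
equivalence_battery <- function(config) {
  pri <- c(session_priors("unimodal", config)[c(1, 4)],
           session_priors("bimodal", config)[c(2, 5)])
  out <- list()
  for (p in pri) for (cue in c(-0.08, 0.03)) for (sl in c(0.07, 0.15)) {
    post <- posterior_update(p$mixture, cue, sl)$base
    if (length(post$weights) > 1L) out[[length(out) + 1L]] <- post
  }
  out
}

# Stack of response densities (rows = battery x power settings) for one
# decision/GA/lapse combination. Deterministic rules are represented by
# their narrow-loss-limit action (the posterior mode).
combo_signature <- function(spec, battery, rgrid, powers, lapse, motor_sd) {
  pw <- if (spec$decision %in% c("SPK", "PSA")) powers else 1
  lam <- if (spec$L) lapse else 0
  rows <- list()
  for (post in battery) {
    ga_post <- apply_ga(post, spec$ga)
    for (k in pw) {
      dens <- switch(spec$decision,
        BDT = stats::dnorm(rgrid, gm_mode(ga_post), motor_sd),
        PPM = dgm(rgrid, gm(ga_post$weights, ga_post$means,
                            sqrt(ga_post$sds^2 + motor_sd^2))),
        SPK = convolved_density(power_density(ga_post, k, rgrid), rgrid, motor_sd),
        PSA = convolved_density(sample_average_density(ga_post, k, rgrid),
                                rgrid, motor_sd))
      if (lam > 0) {
        # the lapse branch draws from the decision-stage distribution's prior;
        # for the family comparison the unapproximated posterior's prior is not
        # in scope, so lapses mix in the same GA posterior shape across combos
        lp <- dgm(rgrid, gm(post$weights, post$means,
                            sqrt(post$sds^2 + motor_sd^2)))
        dens <- (1 - lam) * dens + lam * lp
      }
      rows[[length(rows) + 1L]] <- dens
    }
  }
  do.call(rbind, rows)
}

# Motor convolution of a grid/mixture density evaluated on rgrid.
convolved_density <- function(d, rgrid, motor_sd) {
  if (!is.null(d$mix)) {
    g <- d$mix
    return(dgm(rgrid, gm(g$weights, g$means, sqrt(g$sds^2 + motor_sd^2))))
  }
  dx <- d$x[2] - d$x[1]
  as.numeric(outer(rgrid, d$x, function(a, b) stats::dnorm(a - b, 0, motor_sd)) %*%
               d$pdf) * dx
}

#' Structural design counts of the task and model space
#'
#' Recomputes the printed design quantities from the package machinery:
#' model-set sizes, free-parameter counts, session and dataset condition
#' counts, trial counts and the Gaussian prior SD grid.
#'
#' @param config A [priorcue_config()].
#' @return Named list of counts.
#' @export
design_counts <- function(config = priorcue_config()) {
  plan <- build_session_plan("training", "gaussian", config$repetitions,
                             shuffle = FALSE)
  gauss <- make_gaussian_priors(config)
  list(
    n_basic_models = length(basic_model_set()),
    n_extended_models = extended_model_set(config)$n_distinct,
    n_params_bdt = param_count("BDT"),
    n_params_spk = param_count("SPK"),
    n_params_ppm = param_count("PPM"),
    n_training_trials = nrow(plan),
    n_conditions_session = nrow(unique(plan[c("prior_id", "cue_level")])),
    n_conditions_dataset = 2L * nrow(unique(plan[c("prior_id", "cue_level")])),
    n_dots = config$n_targets,
    gaussian_sd_min = gauss[[1]]$mixture$sds,
    gaussian_sd_max = gauss[[8]]$mixture$sds)
}
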