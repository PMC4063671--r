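#' Robust linear fit with bisquare weights
#'
#' Iteratively reweighted least squares with Tukey's bisquare weighting
#' (via `MASS::rlm`), returning coefficients and their standard errors.
#'
#' @param x,y Numeric vectors (at least 3 points).
#' @return List with `slope`, `intercept`, `se` (named vector).
#' @export
robust_linear_fit <- function(x, y) {
  if (length(x) < 3L || length(y) != length(x)) stop("need >= 3 paired points")
  if (stats::sd(x) == 0) stop("rank-deficient predictor: x is constant")
  fit <- MASS::rlm(y ~ x, psi = MASS::psi.bisquare, maxit = 100)
  cf <- summary(fit)$coefficients
  list(slope = cf[2, 1], intercept = cf[1, 1],
       se = c(intercept = cf[1, 2], slope = cf[2, 2]))
}

#' Cue weights per condition from Gaussian-session responses
#'
#' Robust linear fits of the response against the cue position in
#' coordinates relative to the prior mean, one fit per (prior, cue level)
#' condition of the Gaussian sessions. The slope estimates the weight
#' assigned to the cue; the Bayes-optimal weight
#' `w = sigma_p^2 / (sigma_p^2 + sigma_level^2)` is attached for
#' comparison.
#'
#' @param dataset Trial records with responses.
#' @param config A [priorcue_config()].
#' @return Data frame with one row per (session, prior_id, cue_level):
#'   `slope`, `intercept`, standard errors, `optimal_w`, `prior_sd`.
#' @export
condition_slopes <- function(dataset, config = priorcue_config()) {
  d <- dataset[dataset$prior_class == "gaussian" & !dataset$edge_excluded, ]
  if (nrow(d) == 0L) stop("no Gaussian-session trials")
  sds <- vapply(make_gaussian_priors(config), function(p) p$mixture$sds, numeric(1))
  out <- NULL
  for (se in unique(d$session)) for (id in sort(unique(d$prior_id)))
    for (lev in c("short", "long")) {
      di <- d[d$session == se & d$prior_id == id & d$cue_level == lev, ]
      if (nrow(di) < 3L) next
      fit <- robust_linear_fit(di$cue_x - di$location, di$response_x - di$location)
      sl <- cue_sd_for(lev, config)
      out <- rbind(out, data.frame(
        session = se, prior_id = id, cue_level = lev,
        slope = fit$slope, intercept = fit$intercept,
        se_slope = fit$se[["slope"]], se_intercept = fit$se[["intercept"]],
        prior_sd = sds[id], optimal_w = sds[id]^2 / (sds[id]^2 + sl^2),
        stringsAsFactors = FALSE))
    }
  rownames(out) <- NULL
  out
}

#' Per-condition optimality indices with extremal baselines
#'
#' Mean optimality index per (session, prior, cue level), together with
#' the indices of the two extremal observers: cue-only (response at the
#' cue) and prior-only (response at the optimal target ignoring the cue).
#' Performance above both baselines marks synergistic integration of prior
#' and cue.
#'
#' @param dataset Trial records with responses.
#' @param config A [priorcue_config()].
#' @return Data frame with `mean_index`, `cue_only`, `prior_only` per
#'   condition.
#' @export
optimality_summary <- function(dataset, config = priorcue_config()) {
  d <- dataset[!dataset$edge_excluded & !is.na(dataset$response_x), ]
  priors_by_class <- list()
  for (cl in unique(d$prior_class))
    priors_by_class[[cl]] <- session_priors(cl, config)
  key <- interaction(d$session, d$prior_id, d$cue_level, drop = TRUE)
  out <- NULL
  for (k in levels(key)) {
    di <- d[key == k, ]
    idx <- cue_only <- prior_only <- numeric(nrow(di))
    for (i in seq_len(nrow(di))) {
      tr <- di[i, ]
      prior <- trial_prior(tr, config, priors_by_class[[tr$prior_class]])
      sig <- cue_sd_for(tr$cue_level, config)
      mx <- max_success_probability(prior, tr$cue_x, sig, config$loss)
      idx[i] <- success_probability(prior, tr$cue_x, sig, tr$response_x,
                                    config$loss) / mx$prob
      cue_only[i] <- success_probability(prior, tr$cue_x, sig, tr$cue_x,
                                         config$loss) / mx$prob
      r_prior <- optimal_target(prior, config$loss)
      prior_only[i] <- success_probability(prior, tr$cue_x, sig, r_prior,
                                           config$loss) / mx$prob
    }
    out <- rbind(out, data.frame(
      session = di$session[1], prior_id = di$prior_id[1],
      cue_level = di$cue_level[1], n = nrow(di),
      mean_index = mean(idx), cue_only = mean(cue_only),
      prior_only = mean(prior_only), stringsAsFactors = FALSE))
  }
  rownames(out) <- NULL
  out[order(out$session, out$prior_id, out$cue_level), ]
}

#' Nadaraya-Watson kernel regression
#'
#' Gaussian-kernel local mean with a rule-of-thumb bandwidth.
#'
#' @param x,y Numeric data vectors (at least 10 points).
#' @param x_out Evaluation points (defaults to a grid over `x`).
#' @param bandwidth Kernel bandwidth; default `stats::bw.nrd0(x)`.
#' @return List with `x`, `y` (fitted means) and `bandwidth`.
#' @export
kernel_regression <- function(x, y, x_out = NULL, bandwidth = NULL) {
  if (length(x) < 10L) stop("need at least 10 points")
  if (is.null(bandwidth)) bandwidth <- stats::bw.nrd0(x)
  if (is.null(x_out)) x_out <- seq(min(x), max(x), length.out = 100L)
  fit <- vapply(x_out, function(x0) {
    w <- stats::dnorm((x - x0) / bandwidth)
    sum(w * y) / sum(w)
  }, numeric(1))
  list(x = x_out, y = fit, bandwidth = bandwidth)
}
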