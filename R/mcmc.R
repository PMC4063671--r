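#' Log prior density over observer parameters
#'
#' Factorized prior used for MCMC fits: informative log-normal priors on
#' the motor sd and the cue-estimation sd (hyperparameters from typical
#' sensorimotor magnitudes, configurable), Uniform(0, 1) on the internal
#' likelihood sds and lapse rates (screen units), Uniform(0, 4) on the
#' prior-noise parameter to avoid edge effects, and a Uniform(0, 1] prior
#' on 1/kappa for the decision powers, equivalent to p(kappa) proportional
#' to kappa^-2 on kappa >= 1 (integrable, mildly favouring small powers).
#'
#' @param spec Observer model.
#' @param params Named parameter vector on the natural scale.
#' @param hyper List of hyperparameters: `motor_meanlog`, `motor_sdlog`,
#'   `cue_meanlog`, `cue_sdlog`.
#' @return Scalar log prior density; `-Inf` outside the support.
#' @export
log_prior <- function(spec, params,
                      hyper = list(motor_meanlog = log(0.01), motor_sdlog = 0.5,
                                   cue_meanlog = log(0.01), cue_sdlog = 0.5)) {
  spec <- parse_observer(spec)
  lp <- 0
  for (nm in param_names(spec)) {
    x <- params[[nm]]
    if (!is.finite(x)) return(-Inf)
    lp <- lp + switch(param_kind(nm),
      lik = if (x > 0 && x < 1) 0 else return(-Inf),
      motor = stats::dlnorm(x, hyper$motor_meanlog, hyper$motor_sdlog, log = TRUE),
      cue = stats::dlnorm(x, hyper$cue_meanlog, hyper$cue_sdlog, log = TRUE),
      power = if (x >= 1) -2 * log(x) else return(-Inf),
      weber = if (x > 0 && x <= 4) -log(4) else return(-Inf),
      lapse = if (x > 0 && x < 1) 0 else return(-Inf))
  }
  lp
}

param_kind <- function(nm) {
  if (grepl("^lik_sd", nm)) "lik"
  else if (nm == "motor_sd") "motor"
  else if (grepl("^cue_est_sd", nm)) "cue"
  else if (grepl("^(kappa|psa_k)", nm)) "power"
  else if (grepl("^weber", nm)) "weber"
  else if (grepl("^lapse", nm)) "lapse"
  else stop("unknown parameter: ", nm)
}

slice_width <- function(nm) {
  switch(param_kind(nm), lik = 0.05, motor = 0.01, cue = 0.01,
         power = 1, weber = 0.3, lapse = 0.1)
}

#' Coordinate-wise slice sampler
#'
#' Univariate slice sampling with stepping-out and shrinkage applied to
#' each coordinate in turn, run as several parallel chains from different
#' starting points. Deterministic given the seed.
#'
#' @param log_target Function of a named numeric vector returning the log
#'   target density (`-Inf` outside the support).
#' @param init Matrix of starting points (`n_chains` x `n_params`, named
#'   columns) or a single named vector used for every chain.
#' @param n_chains Number of chains.
#' @param burn_in Discarded sweeps per chain.
#' @param n_samples Kept sweeps per chain.
#' @param seed Integer seed.
#' @param widths Initial slice widths per parameter (defaults by parameter
#'   kind).
#' @param max_step_out Maximum stepping-out expansions per side.
#' @return List with `chains` (array `n_chains` x `n_samples` x
#'   `n_params`), `log_target` (matrix `n_chains` x `n_samples`).
#' @export
slice_sample <- function(log_target, init, n_chains = 3L, burn_in = 100L,
                         n_samples = 500L, seed = 1L, widths = NULL,
                         max_step_out = 20L) {
  set.seed(seed)
  if (is.null(dim(init)))
    init <- matrix(init, n_chains, length(init), byrow = TRUE,
                   dimnames = list(NULL, names(init)))
  nm <- colnames(init)
  p <- length(nm)
  if (is.null(widths)) widths <- vapply(nm, slice_width, numeric(1))
  widths <- rep_len(widths, p)
  chains <- array(NA_real_, c(n_chains, n_samples, p),
                  dimnames = list(NULL, NULL, nm))
  lt <- matrix(NA_real_, n_chains, n_samples)
  for (c_i in seq_len(n_chains)) {
    x <- stats::setNames(init[c_i, ], nm)
    fx <- log_target(x)
    if (!is.finite(fx)) stop("log target not finite at chain ", c_i, " start")
    for (s in seq_len(burn_in + n_samples)) {
      for (j in seq_len(p)) {
        y <- fx - stats::rexp(1)
        w <- widths[j]
        L <- x[j] - stats::runif(1) * w
        R <- L + w
        xl <- x; xr <- x
        for (k in seq_len(max_step_out)) {
          xl[j] <- L
          if (log_target(xl) <= y) break
          L <- L - w
        }
        for (k in seq_len(max_step_out)) {
          xr[j] <- R
          if (log_target(xr) <= y) break
          R <- R + w
        }
        repeat {
          x1 <- x
          x1[j] <- stats::runif(1, L, R)
          f1 <- log_target(x1)
          if (is.finite(f1) && f1 > y) { x <- x1; fx <- f1; break }
          if (x1[j] < x[j]) L <- x1[j] else R <- x1[j]
          if (R - L < 1e-12) { break }
        }
      }
      if (s > burn_in) {
        chains[c_i, s - burn_in, ] <- x
        lt[c_i, s - burn_in] <- fx
      }
    }
  }
  list(chains = chains, log_target = lt)
}

#' Gelman-Rubin potential scale reduction
#'
#' Between/within-chain variance ratio per parameter; values near 1 suggest
#' convergence.
#'
#' @param chains Array `n_chains` x `n_samples` x `n_params` (or a matrix
#'   for one parameter).
#' @return Named vector of R-hat values; degenerate zero-variance
#'   parameters yield `NaN` with a warning.
#' @export
gelman_rubin <- function(chains) {
  if (length(dim(chains)) == 2L) chains <- array(chains, c(dim(chains), 1L))
  m <- dim(chains)[1]; n <- dim(chains)[2]; p <- dim(chains)[3]
  if (m < 2L || n < 10L) stop("need at least 2 chains of 10 samples")
  out <- vapply(seq_len(p), function(j) {
    x <- chains[, , j, drop = FALSE]
    means <- rowMeans(x[, , 1])
    W <- mean(apply(x[, , 1], 1, stats::var))
    B_over_n <- stats::var(means)
    if (W <= 0) return(NaN)
    sqrt(((n - 1) / n * W + B_over_n) / W)
  }, numeric(1))
  names(out) <- dimnames(chains)[[3]]
  if (anyNA(out)) warning("zero within-chain variance for some parameter(s)")
  out
}

#' Deviance information criterion from MCMC output
#'
#' `DIC = 2 * mean(D) - D(theta_hat)` with deviance `D = -2 log L`;
#' `p_d = mean(D) - D(theta_hat)` is the effective number of parameters.
#' The point estimate `theta_hat` is a per-parameter trimmed mean (10% per
#' side by default), robust to occasional outlier samples.
#'
#' @param samples Matrix of posterior draws (rows = draws, named columns).
#' @param log_liks Log-likelihood value of each draw.
#' @param log_lik_fn Function evaluating the log-likelihood at a named
#'   parameter vector (used once, at `theta_hat`).
#' @param trim Trimming fraction per side for the point estimate.
#' @return List with `dic`, `p_d`, `theta_hat`.
#' @export
dic <- function(samples, log_liks, log_lik_fn, trim = 0.1) {
  theta_hat <- apply(samples, 2, mean, trim = trim)
  mean_dev <- mean(-2 * log_liks)
  dev_hat <- -2 * as.numeric(log_lik_fn(theta_hat))
  list(dic = 2 * mean_dev - dev_hat, p_d = mean_dev - dev_hat,
       theta_hat = theta_hat)
}

#' Fit an observer model to a dataset by slice-sampling MCMC
#'
#' Samples the posterior over the model's parameters (likelihood from
#' [make_loglik()], prior from [log_prior()]) with three parallel chains
#' started from dispersed points, and summarizes convergence (R-hat), DIC
#' and a robust (trimmed-mean) point estimate.
#'
#' @param spec Observer model.
#' @param dataset Trial records with responses.
#' @param config A [priorcue_config()].
#' @param seed Integer seed.
#' @param budget List with `n_chains`, `burn_in`, `n_samples`.
#' @param hyper Prior hyperparameters, see [log_prior()].
#' @return Object of class `"mcmc_result"`: `chains`, `samples` (flattened
#'   draws), `log_liks`, `rhat`, `dic`, `p_d`, `theta_hat`, `spec`.
#' @export
fit_observer <- function(spec, dataset, config = priorcue_config(), seed = 1L,
                         budget = list(n_chains = 3L, burn_in = 200L,
                                       n_samples = 600L),
                         hyper = NULL) {
  spec <- parse_observer(spec)
  if (is.null(hyper))
    hyper <- list(motor_meanlog = log(0.01), motor_sdlog = 0.5,
                  cue_meanlog = log(0.01), cue_sdlog = 0.5)
  loglik <- make_loglik(spec, dataset, config)
  lp <- function(th) log_prior(spec, th, hyper)
  log_target <- function(th) {
    pr <- lp(th)
    if (!is.finite(pr)) return(-Inf)
    pr + as.numeric(loglik(th))
  }
  nm <- param_names(spec)
  set.seed(seed)
  init <- t(vapply(seq_len(budget$n_chains), function(i) {
    for (try_i in 1:50) {
      th <- clamp_params(default_params(spec) *
                           exp(stats::rnorm(length(nm), 0, 0.25)))
      if (is.finite(log_target(th))) return(th)
    }
    stop("could not initialize chain ", i)
  }, default_params(spec)))
  colnames(init) <- nm
  run <- slice_sample(log_target, init, n_chains = budget$n_chains,
                      burn_in = budget$burn_in, n_samples = budget$n_samples,
                      seed = seed + 1L)
  samples <- do.call(rbind, lapply(seq_len(budget$n_chains),
                                   function(c_i) run$chains[c_i, , ]))
  colnames(samples) <- nm
  # log-likelihoods recovered from the stored log target minus the prior
  log_liks <- as.numeric(t(run$log_target)) -
    apply(samples, 1, function(th) lp(stats::setNames(th, nm)))
  d <- dic(samples, log_liks, function(th) loglik(stats::setNames(th, nm)))
  structure(list(spec = spec, chains = run$chains, samples = samples,
                 log_liks = log_liks, rhat = gelman_rubin(run$chains),
                 dic = d$dic, p_d = d$p_d, theta_hat = d$theta_hat,
                 budget = budget, seed = seed),
            class = "mcmc_result")
}

#' @export
print.mcmc_result <- function(x, ...) {
  cat("MCMC fit of", x$spec$id, "-", nrow(x$samples), "draws\n")
  cat("DIC:", round(x$dic, 1), " p_d:", round(x$p_d, 2),
      " max R-hat:", round(max(x$rhat), 3), "\n")
  print(round(x$theta_hat, 4))
  invisible(x)
}

#' Multi-start MAP search
#'
#' Optional sanity check before or after sampling: Nelder-Mead
#' maximization of the log posterior from several random starting points.
#'
#' @inheritParams fit_observer
#' @param n_starts Number of random restarts.
#' @return List with `par` (best point) and `value` (log posterior).
#' @export
map_search <- function(spec, dataset, config = priorcue_config(), seed = 1L,
                       n_starts = 30L, hyper = NULL) {
  spec <- parse_observer(spec)
  if (is.null(hyper))
    hyper <- list(motor_meanlog = log(0.01), motor_sdlog = 0.5,
                  cue_meanlog = log(0.01), cue_sdlog = 0.5)
  loglik <- make_loglik(spec, dataset, config)
  nm <- param_names(spec)
  obj <- function(th) {
    th <- stats::setNames(th, nm)
    pr <- log_prior(spec, th, hyper)
    if (!is.finite(pr)) return(1e10)
    -(pr + as.numeric(loglik(th)))
  }
  set.seed(seed)
  best <- NULL
  for (i in seq_len(n_starts)) {
    th0 <- clamp_params(default_params(spec) * exp(stats::rnorm(length(nm), 0, 0.4)))
    fit <- try(stats::optim(th0, obj, method = "Nelder-Mead",
                            control = list(maxit = 500)), silent = TRUE)
    if (inherits(fit, "try-error")) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) stop("all MAP restarts failed")
  list(par = stats::setNames(best$par, nm), value = -best$value)
}
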