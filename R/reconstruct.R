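#' Reconstruction specification
#'
#' Settings for the nonparametric group-prior reconstruction: the prior is
#' represented as a mixture of `M` Gaussian components with means equally
#' spaced over `bounds` and common SD equal to the grid spacing; only the
#' mixing weights are free (flat prior over their log values), optionally
#' constrained to be symmetric about the prior mean.
#'
#' @param M Number of mixture components (>= 2).
#' @param bounds Range spanned by the component means (canonical,
#'   prior-mean-centred coordinates); `NULL` derives it from the true
#'   discretized prior range of the condition.
#' @param symmetric Enforce symmetric weights?
#' @param spec Observer model assumed for the likelihood (the decision
#'   rule and lapse of `"SPK-L"`; subject parameters are fixed).
#' @return List of class `"recon_spec"`.
#' @export
recon_spec <- function(M = 30L, bounds = NULL, symmetric = FALSE,
                       spec = "SPK-L") {
  if (M < 2L) stop("M must be >= 2")
  structure(list(M = as.integer(M), bounds = bounds, symmetric = symmetric,
                 spec = parse_observer(spec)), class = "recon_spec")
}

#' Nonparametric reconstruction of a group prior
#'
#' Slice-samples the mixing weights of a many-component Gaussian-mixture
#' representation of one condition's prior (log-weight parameterization,
#' sum-to-one enforced, optional symmetry constraint), under the pooled
#' likelihood of all subjects' responses in that condition with each
#' subject's stochastic-posterior-with-lapse parameters held fixed.
#' Trials are mapped to canonical coordinates (relative to the prior mean,
#' mirrored for flipped trials) so all subjects share one prior shape.
#'
#' @param datasets List of subjects: each a list with `data` (trial
#'   records) and `theta` (fixed SPK-L-compatible named parameters), e.g.
#'   `subject_sim` objects.
#' @param prior_class,prior_id Condition whose prior is reconstructed
#'   (test-session trials are used).
#' @param rspec A [recon_spec()].
#' @param budget List with `n_chains`, `burn_in`, `n_samples`.
#' @param seed Integer seed.
#' @param config A [priorcue_config()].
#' @param grid_points Number of points of the internal posterior grid.
#' @param sessions Sessions whose trials enter the likelihood; group priors
#'   are session-specific, so the default uses the test session only.
#' @return List with `weights` (posterior draws, rows = samples),
#'   `mean_prior` (a [gm()]), `component_means`, `component_sd`,
#'   `moments` (per-draw mean/variance/skewness/kurtosis), `rhat`
#'   (computed on the per-draw prior mean and variance: individual mixing
#'   weights are only weakly identified and their chains are not the
#'   relevant convergence target).
#' @export
reconstruct_priors <- function(datasets, prior_class, prior_id,
                               rspec = recon_spec(),
                               budget = list(n_chains = 3L, burn_in = 30L,
                                             n_samples = 90L),
                               seed = 1L, config = priorcue_config(),
                               grid_points = 80L, sessions = "test") {
  spec <- rspec$spec
  priors <- session_priors(prior_class, config)
  canon <- priors[[prior_id]]$mixture
  qs <- discretize_prior(canon, config$n_targets)
  bounds <- rspec$bounds
  if (is.null(bounds)) bounds <- range(qs)
  M <- rspec$M
  mu_g <- seq(bounds[1], bounds[2], length.out = M)
  s_c <- mu_g[2] - mu_g[1]

  # pooled canonical trials with per-trial fixed observer parameters
  trials <- NULL
  for (sub in datasets) {
    d <- sub$data
    d <- d[d$prior_class == prior_class & d$prior_id == prior_id &
             d$session %in% sessions &
             !d$edge_excluded & !is.na(d$response_x), , drop = FALSE]
    if (nrow(d) == 0L) next
    flip <- ifelse(d$flipped, -1, 1)
    th <- sub$theta
    tr <- data.frame(
      cue = flip * (d$cue_x - d$location),
      r = flip * (d$response_x - d$location),
      lik_sd = vapply(seq_len(nrow(d)), function(i)
        subj_lik_sd(th, d[i, ]), numeric(1)),
      kappa = vapply(seq_len(nrow(d)), function(i)
        session_par(th, d[i, ], "kappa"), numeric(1)),
      lapse = if (spec$L) vapply(seq_len(nrow(d)), function(i)
        session_par(th, d[i, ], "lapse"), numeric(1)) else 0,
      motor = th[["motor_sd"]])
    trials <- rbind(trials, tr)
  }
  if (is.null(trials) || nrow(trials) == 0L)
    stop("no usable trials for the requested condition")
  Tn <- nrow(trials)

  # precomputed per-(trial, component) posterior pieces
  A <- outer(seq_len(Tn), seq_len(M), function(t, j)
    stats::dnorm(trials$cue[t], mu_g[j], sqrt(s_c^2 + trials$lik_sd[t]^2)))
  m_tj <- outer(seq_len(Tn), seq_len(M), function(t, j)
    (mu_g[j] * trials$lik_sd[t]^2 + trials$cue[t] * s_c^2) /
      (s_c^2 + trials$lik_sd[t]^2))
  v_t <- s_c^2 * trials$lik_sd^2 / (s_c^2 + trials$lik_sd^2)
  pad <- 4 * max(s_c, stats::sd(trials$r))
  gx <- seq(bounds[1] - pad, bounds[2] + pad, length.out = grid_points)
  # B[(t,g), j] = A_tj * N(gx_g | m_tj, v_t); K[t, g] = motor kernel at r_t
  B <- matrix(0, Tn * grid_points, M)
  for (j in seq_len(M))
    B[, j] <- as.numeric(t(A[, j] * outer(m_tj[, j], gx, function(m, g)
      stats::dnorm(g, m, sqrt(v_t)))))
  K <- outer(seq_len(Tn), seq_len(grid_points), function(t, g)
    stats::dnorm(trials$r[t], gx[g], trials$motor[t]))
  L <- outer(seq_len(Tn), seq_len(M), function(t, j)
    stats::dnorm(trials$r[t], mu_g[j], sqrt(s_c^2 + trials$motor[t]^2)))
  kap <- trials$kappa
  lam <- trials$lapse
  eps <- config$regularization_eps

  # log-weight parameterization: free coordinates -> full simplex weights
  if (rspec$symmetric) {
    half <- ceiling(M / 2)
    expand <- function(phi_free) {
      phi <- numeric(M)
      phi[seq_len(half)] <- c(0, phi_free)
      phi[M:(M - half + 1)] <- phi[seq_len(half)]
      phi
    }
    n_free <- half - 1L
  } else {
    expand <- function(phi_free) c(0, phi_free)
    n_free <- M - 1L
  }
  to_weights <- function(phi_free) {
    phi <- expand(phi_free)
    w <- exp(phi - max(phi))
    w / sum(w)
  }

  log_target <- function(phi_free) {
    if (any(abs(phi_free) > 12)) return(-Inf)
    w <- to_weights(phi_free)
    P <- matrix(B %*% w, Tn, grid_points, byrow = TRUE)
    U <- exp(kap * log(pmax(P, 1e-300)))
    core <- rowSums(U * K) / rowSums(U)
    p <- (1 - lam) * core + lam * as.numeric(L %*% w)
    sum(log(p + eps))
  }

  set.seed(seed)
  init <- matrix(stats::rnorm(budget$n_chains * n_free, 0, 0.5),
                 budget$n_chains, n_free)
  colnames(init) <- paste0("phi", seq_len(n_free))
  run <- slice_sample(log_target, init, n_chains = budget$n_chains,
                      burn_in = budget$burn_in, n_samples = budget$n_samples,
                      seed = seed + 1L, widths = rep(1, n_free))
  flat <- do.call(rbind, lapply(seq_len(budget$n_chains),
                                function(c_i) run$chains[c_i, , ]))
  W <- t(apply(flat, 1, to_weights))
  moments <- t(apply(W, 1, function(w) gm_moments(gm(w, mu_g, rep(s_c, M)))))
  # convergence is assessed on the functionals of interest
  mom_chains <- array(NA_real_, c(budget$n_chains, budget$n_samples, 2L),
                      dimnames = list(NULL, NULL, c("mean", "variance")))
  for (c_i in seq_len(budget$n_chains)) {
    rows <- (c_i - 1L) * budget$n_samples + seq_len(budget$n_samples)
    mom_chains[c_i, , ] <- moments[rows, c("mean", "variance")]
  }
  rh <- gelman_rubin(mom_chains)
  if (max(rh, na.rm = TRUE) > 1.1)
    warning("reconstruction chains may not have converged (max R-hat ",
            round(max(rh, na.rm = TRUE), 3), " on the prior moments); ",
            "increase the budget")
  list(weights = W,
       mean_prior = gm(colMeans(W), mu_g, rep(s_c, M)),
       component_means = mu_g, component_sd = s_c,
       moments = moments, rhat = rh, n_trials = Tn)
}
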