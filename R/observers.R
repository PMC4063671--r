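#' Observer model specification
#'
#' A point in the factorial model space: a decision rule (`BDT` Bayesian
#' decision theory, `SPK` stochastic posterior with free power, `PPM`
#' posterior probability matching, `PSA` posterior sampling average), an
#' optional single-Gaussian approximation of the posterior (`MV`
#' moment-matched, `LA` Laplace), and optional factors `S` (cue-estimation
#' sensory noise), `P` (noisy estimation of the prior parameters) and `L`
#' (lapse). Canonical model strings read e.g. `"SPK-P-L"` or `"PPM-MV-L"`.
#'
#' @param decision One of `"BDT"`, `"SPK"`, `"PPM"`, `"PSA"`.
#' @param ga Gaussian approximation: `"none"`, `"MV"` or `"LA"`.
#' @param S,P,L Logical factor switches.
#' @return Object of class `"observer_spec"`.
#' @export
observer_spec <- function(decision, ga = "none", S = FALSE, P = FALSE, L = FALSE) {
  decision <- match.arg(decision, c("BDT", "SPK", "PPM", "PSA"))
  ga <- match.arg(ga, c("none", "MV", "LA"))
  out <- structure(list(decision = decision, ga = ga,
                        S = isTRUE(S), P = isTRUE(P), L = isTRUE(L)),
                   class = "observer_spec")
  out$id <- render_observer(out)
  out
}

#' @rdname observer_spec
#' @param x A model string such as `"SPK-P-L"`.
#' @export
parse_observer <- function(x) {
  if (inherits(x, "observer_spec")) return(x)
  toks <- strsplit(x, "-", fixed = TRUE)[[1]]
  if (!toks[1] %in% c("BDT", "SPK", "PPM", "PSA"))
    stop("model string must start with a decision level: ", x)
  rest <- toks[-1]
  known <- c("MV", "LA", "S", "P", "L")
  if (any(!rest %in% known) || anyDuplicated(rest))
    stop("malformed model string: ", x)
  if (all(c("MV", "LA") %in% rest)) stop("MV and LA are exclusive: ", x)
  observer_spec(toks[1],
                ga = if ("MV" %in% rest) "MV" else if ("LA" %in% rest) "LA" else "none",
                S = "S" %in% rest, P = "P" %in% rest, L = "L" %in% rest)
}

render_observer <- function(spec) {
  paste(c(spec$decision,
          if (spec$ga != "none") spec$ga,
          if (spec$S) "S", if (spec$P) "P", if (spec$L) "L"),
        collapse = "-")
}

#' @export
print.observer_spec <- function(x, ...) {
  cat("Observer model", x$id, "with", param_count(x), "free parameters\n")
  invisible(x)
}

#' Free parameters of an observer model
#'
#' Parameter sharing across the training and test sessions follows the
#' task's conventions: the motor sd is shared; the internal likelihood sds
#' need three values (short/long in training, short in test; the long test
#' value is tied by the training long/short ratio); every other factor
#' contributes one parameter per session. The decision power (`kappa` for
#' SPK, the sample count `k` for PSA) is session-specific.
#'
#' @param spec An [observer_spec()] or model string.
#' @return `param_names()`: character vector; `param_count()`: integer.
#' @export
param_names <- function(spec) {
  spec <- parse_observer(spec)
  nm <- c("lik_sd_short_train", "lik_sd_long_train", "lik_sd_short_test", "motor_sd")
  if (spec$decision == "SPK") nm <- c(nm, "kappa_train", "kappa_test")
  if (spec$decision == "PSA") nm <- c(nm, "psa_k_train", "psa_k_test")
  if (spec$S) nm <- c(nm, "cue_est_sd_train", "cue_est_sd_test")
  if (spec$P) nm <- c(nm, "weber_prior_train", "weber_prior_test")
  if (spec$L) nm <- c(nm, "lapse_train", "lapse_test")
  nm
}

#' @rdname param_names
#' @export
param_count <- function(spec) length(param_names(spec))

#' Typical parameter values for an observer model
#'
#' Synthetic defaults in plausible magnitudes for simulation and recovery
#' experiments: internal likelihood sds slightly mismatched from the true
#' cue sds, about a centimetre of motor noise, moderate decision noise,
#' prior-estimation noise and a few percent of lapses.
#'
#' @inheritParams param_names
#' @return Named numeric vector on the natural scale.
#' @export
default_params <- function(spec) {
  spec <- parse_observer(spec)
  vals <- c(lik_sd_short_train = 0.075, lik_sd_long_train = 0.16,
            lik_sd_short_test = 0.075, motor_sd = 0.012,
            kappa_train = 2.5, kappa_test = 2,
            psa_k_train = 2, psa_k_test = 2,
            cue_est_sd_train = 0.01, cue_est_sd_test = 0.01,
            weber_prior_train = 0.15, weber_prior_test = 0.2,
            lapse_train = 0.03, lapse_test = 0.05)
  vals[param_names(spec)]
}

# --- per-trial parameter resolution --------------------------------------

is_train <- function(trial) trial$session == "training"

# Subjective likelihood sd for the trial's session and cue level, with the
# long test value tied by the training long/short ratio.
subj_lik_sd <- function(params, trial) {
  if (is_train(trial)) {
    if (trial$cue_level == "short") params[["lik_sd_short_train"]]
    else params[["lik_sd_long_train"]]
  } else {
    if (trial$cue_level == "short") params[["lik_sd_short_test"]]
    else params[["lik_sd_short_test"]] *
      params[["lik_sd_long_train"]] / params[["lik_sd_short_train"]]
  }
}

# Cue-estimation sd (factor S): session parameter for short cues, long cues
# tied by the cue-distance ratio (Weber-like scaling with distance).
cue_est_sd <- function(spec, params, trial, config) {
  if (!spec$S) return(0)
  base <- if (is_train(trial)) params[["cue_est_sd_train"]] else params[["cue_est_sd_test"]]
  if (trial$cue_level == "short") base
  else base * config$cue_dist_long / config$cue_dist_short
}

session_par <- function(params, trial, stem) {
  key <- paste0(stem, if (is_train(trial)) "_train" else "_test")
  if (key %in% names(params)) params[[key]] else NA_real_
}

decision_power <- function(spec, params, trial) {
  switch(spec$decision,
         BDT = Inf,
         PPM = 1,
         SPK = session_par(params, trial, "kappa"),
         PSA = session_par(params, trial, "psa_k"))
}

# Realized trial prior from the stored record columns.
trial_prior <- function(trial, config, priors = NULL) {
  if (is.null(priors)) priors <- session_priors(trial$prior_class, config)
  realize_prior(priors[[trial$prior_id]], trial$location, trial$flipped)
}

# --- factor P: structured noise on the prior parameters ------------------

# Number of latent standard-normal variables factor P attaches to a prior.
n_p_latents <- function(spec, prior) {
  if (!spec$P) return(0L)
  if (length(prior$weights) == 2L) 2L else 1L
}

# Perturb the internal representation of the prior: log-normal noise on the
# width for single-peak priors (and on the overall scale for many-component
# platykurtic priors), independent log-normal noise on the two weights for
# two-component priors.
perturb_prior <- function(prior, eta, z) {
  if (eta == 0 || length(z) == 0L) return(prior)
  M <- length(prior$weights)
  if (M == 1L) return(gm(1, prior$means, prior$sds * exp(eta * z[1])))
  if (M == 2L) {
    w <- prior$weights * exp(eta * z)
    return(gm(w / sum(w), prior$means, prior$sds))
  }
  mu <- gm_mean(prior)
  s <- exp(eta * z[1])
  gm(prior$weights, mu + (prior$means - mu) * s, prior$sds * s)
}

# --- decision machinery ---------------------------------------------------

apply_ga <- function(post, ga) {
  switch(ga, none = post, MV = mv_approx(post), LA = laplace_approx(post))
}

# Target-choice distribution conditional on the internal measurements.
# Returns one of: list(type="delta", at=), list(type="mix", g=gm),
# list(type="grid", x=, pdf=).
choice_distribution <- function(spec, params, prior, cue_m, lik_sd_eff, config,
                                trial, grid = NULL) {
  post <- posterior_update(prior, cue_m, lik_sd_eff)$base
  post <- apply_ga(post, spec$ga)
  pw <- decision_power(spec, params, trial)
  if (spec$decision == "BDT") {
    return(list(type = "delta", at = optimal_target(post, config$loss)))
  }
  if (length(post$weights) == 1L) {
    k <- if (is.finite(pw)) pw else 1
    return(list(type = "mix", g = gm(1, post$means, post$sds / sqrt(max(k, 1e-12)))))
  }
  d <- if (spec$decision == "PSA") sample_average_density(post, pw, grid)
       else power_density(post, pw, grid)
  if (!is.null(d$mix)) list(type = "mix", g = d$mix)
  else list(type = "grid", x = d$x, pdf = d$pdf)
}

# Density of the motor-noise convolved choice at response points r; the
# lapse branch mixes in the (internal) prior before motor convolution.
response_from_choice <- function(choice, r, motor_sd, lapse = 0, lapse_prior = NULL) {
  core <- switch(choice$type,
    delta = stats::dnorm(r, choice$at, motor_sd),
    mix = dgm(r, gm(choice$g$weights, choice$g$means,
                    sqrt(choice$g$sds^2 + motor_sd^2))),
    grid = {
      dx <- choice$x[2] - choice$x[1]
      as.numeric(outer(r, choice$x, function(a, b)
        stats::dnorm(a - b, 0, motor_sd)) %*% choice$pdf) * dx
    })
  if (lapse > 0) {
    lp <- dgm(r, gm(lapse_prior$weights, lapse_prior$means,
                    sqrt(lapse_prior$sds^2 + motor_sd^2)))
    (1 - lapse) * core + lapse * lp
  } else core
}

#' Target-choice density of an observer on a trial
#'
#' The distribution of intended targets conditional on the displayed cue
#' (internal measurements set to their noiseless values): the decision rule
#' applied to the (possibly Gaussian-approximated) subjective posterior,
#' with the lapse branch mixed in. Motor noise and the S/P latent
#' marginalizations belong to [response_density()].
#'
#' @param spec An [observer_spec()] or model string.
#' @param params Named parameter vector ([default_params()]).
#' @param trial One trial record row.
#' @param config A [priorcue_config()].
#' @param grid Optional evaluation grid.
#' @return A `grid_density` object (a delta choice is returned as a
#'   `grid_density` with a `delta` attribute).
#' @export
target_choice_density <- function(spec, params, trial, config = priorcue_config(),
                                  grid = NULL) {
  spec <- parse_observer(spec)
  prior <- trial_prior(trial, config)
  sl <- subj_lik_sd(params, trial)
  ss <- cue_est_sd(spec, params, trial, config)
  ch <- choice_distribution(spec, params, prior, trial$cue_x, sqrt(sl^2 + ss^2),
                            config, trial, grid)
  lam <- if (spec$L) session_par(params, trial, "lapse") else 0
  if (ch$type == "delta" && lam == 0)
    return(structure(grid_density(ch$at, Inf), delta = ch$at))
  if (is.null(grid)) grid <- gm_grid(prior)
  pdf <- switch(ch$type,
                delta = { p <- numeric(length(grid)); p },
                mix = dgm(grid, ch$g),
                grid = stats::approx(ch$x, ch$pdf, xout = grid, yleft = 0, yright = 0)$y)
  if (lam > 0) pdf <- (1 - lam) * pdf + lam * dgm(grid, prior)
  out <- grid_density(grid, pdf)
  if (ch$type == "delta") attr(out, "delta") <- ch$at
  if (ch$type == "delta") attr(out, "delta_weight") <- 1 - lam
  out
}

# --- Gauss-Hermite quadrature --------------------------------------------

# Nodes/weights of n-point Gauss-Hermite quadrature (physicists' weight
# exp(-x^2)), via the Golub-Welsch eigenvalue method; cached per order.
gauss_hermite <- local({
  cache <- list()
  function(n) {
    key <- as.character(n)
    if (!is.null(cache[[key]])) return(cache[[key]])
    i <- seq_len(n - 1)
    J <- matrix(0, n, n)
    J[cbind(i, i + 1)] <- sqrt(i / 2)
    J[cbind(i + 1, i)] <- sqrt(i / 2)
    e <- eigen(J, symmetric = TRUE)
    x <- e$values
    w <- sqrt(pi) * e$vectors[1, ]^2
    ord <- order(x)
    out <- list(x = x[ord], w = w[ord])
    cache[[key]] <<- out
    out
  }
})

# Standard-normal quadrature nodes: z ~ N(0,1), weights sum to 1.
gh_normal <- function(n) {
  gh <- gauss_hermite(n)
  list(z = sqrt(2) * gh$x, w = gh$w / sqrt(pi))
}

#' Response probability density of an observer on a trial
#'
#' The observable response distribution: the target choice convolved with
#' Gaussian motor noise and marginalized over the latent internal
#' measurements of factor S (Gaussian noise on the cue position) and factor
#' P (log-normal noise on the prior parameters) by Gauss-Hermite
#' quadrature.
#'
#' @inheritParams target_choice_density
#' @param r Response positions at which to evaluate; `NULL` returns the
#'   density on a grid.
#' @return Numeric vector of densities at `r`, or a `grid_density`.
#' @export
response_density <- function(spec, params, trial, config = priorcue_config(),
                             r = NULL, grid = NULL) {
  spec <- parse_observer(spec)
  prior <- trial_prior(trial, config)
  if (is.null(r)) {
    if (is.null(grid)) grid <- gm_grid(prior, step = 1e-3)
    return(grid_density(grid, response_density(spec, params, trial, config, r = grid)))
  }
  sl <- subj_lik_sd(params, trial)
  ss <- cue_est_sd(spec, params, trial, config)
  lik_eff <- sqrt(sl^2 + ss^2)
  motor <- params[["motor_sd"]]
  lam <- if (spec$L) session_par(params, trial, "lapse") else 0
  eta <- if (spec$P) session_par(params, trial, "weber_prior") else 0
  np <- n_p_latents(spec, prior)
  ns <- if (spec$S && ss > 0) 1L else 0L
  dims <- np + ns
  if (dims == 0L) {
    ch <- choice_distribution(spec, params, prior, trial$cue_x, lik_eff,
                              config, trial)
    return(response_from_choice(ch, r, motor, lam, prior))
  }
  ord <- if (dims == 1L) config$gh_order else if (dims == 2L) 12L else 8L
  gh <- gh_normal(ord)
  nodes <- as.matrix(do.call(expand.grid, rep(list(seq_len(ord)), dims)))
  out <- numeric(length(r))
  for (i in seq_len(nrow(nodes))) {
    idx <- nodes[i, ]
    wgt <- prod(gh$w[idx])
    zs <- gh$z[idx]
    cue_m <- trial$cue_x
    if (ns == 1L) { cue_m <- trial$cue_x + ss * zs[1]; zp <- zs[-1] } else zp <- zs
    pr_i <- if (np > 0L) perturb_prior(prior, eta, zp) else prior
    ch <- choice_distribution(spec, params, pr_i, cue_m, lik_eff, config, trial)
    out <- out + wgt * response_from_choice(ch, r, motor, lam, pr_i)
  }
  out
}

#' Closed-form response distribution for Gaussian priors
#'
#' For a single-Gaussian trial prior and the BDT/SPK/PPM decision rules
#' (optionally with factor S, without factor P) the response distribution
#' is exactly Gaussian: mean at the reliability-weighted combination of
#' prior mean and cue, variance combining the power-scaled posterior
#' variance, the propagated cue-measurement variance and the motor
#' variance. BDT is the `kappa = Inf` limit, PPM is `kappa = 1`.
#'
#' @inheritParams target_choice_density
#' @return List with `mean` and `sd` (the lapse branch, when present, is
#'   returned as `lapse`, `lapse_mean`, `lapse_sd`).
#' @export
gaussian_closed_form_response <- function(spec, params, trial,
                                          config = priorcue_config()) {
  spec <- parse_observer(spec)
  prior <- trial_prior(trial, config)
  if (length(prior$weights) != 1L)
    stop("closed form requires a single-Gaussian trial prior")
  if (spec$P) stop("closed form does not cover factor P")
  # for a Gaussian posterior the MV and LA approximations are the identity
  sl <- subj_lik_sd(params, trial)
  ss <- cue_est_sd(spec, params, trial, config)
  kap <- decision_power(spec, params, trial)
  mu_p <- prior$means; s2p <- prior$sds^2
  lik2 <- sl^2 + ss^2
  w <- s2p / (s2p + lik2)
  post_var <- s2p * lik2 / (s2p + lik2)
  m <- mu_p + w * (trial$cue_x - mu_p)
  v <- w^2 * ss^2 + (if (is.finite(kap)) post_var / kap else 0) + params[["motor_sd"]]^2
  out <- list(mean = m, sd = sqrt(v))
  if (spec$L) {
    out$lapse <- session_par(params, trial, "lapse")
    out$lapse_mean <- mu_p
    out$lapse_sd <- sqrt(s2p + params[["motor_sd"]]^2)
  }
  out
}

#' Log-likelihood of a dataset under an observer model
#'
#' Sum over non-edge trials of the log regularized response probability;
#' each trial's density is floored by mixing in `eps` (the standard-normal
#' density five standard deviations out), bounding single-trial
#' log-probabilities from below.
#'
#' @inheritParams target_choice_density
#' @param dataset Data frame of trial records with responses.
#' @return Scalar log-likelihood with attribute `per_trial`.
#' @export
log_likelihood <- function(spec, params, dataset, config = priorcue_config()) {
  spec <- parse_observer(spec)
  dataset <- dataset[!dataset$edge_excluded, , drop = FALSE]
  if (nrow(dataset) == 0L) return(structure(0, per_trial = numeric(0)))
  eps <- config$regularization_eps
  ll <- make_loglik(spec, dataset, config)(params)
  pt <- attr(ll, "per_trial")
  bad <- !is.finite(pt)
  if (any(bad))
    stop("non-finite response density at trial(s) ",
         paste(utils::head(which(bad)), collapse = ", "))
  ll
}

#' Compile a fast log-likelihood closure for a dataset
#'
#' Precomputes per-trial constants; the returned closure maps a named
#' parameter vector to the regularized log-likelihood. Single-Gaussian
#' prior trials use the closed form (with Gauss-Hermite marginalization
#' over factor P), mixture-prior trials go through the generic
#' [response_density()] path.
#'
#' @inheritParams log_likelihood
#' @return Function of `params` returning the log-likelihood with a
#'   `per_trial` attribute.
#' @export
make_loglik <- function(spec, dataset, config = priorcue_config()) {
  spec <- parse_observer(spec)
  dataset <- dataset[!dataset$edge_excluded, , drop = FALSE]
  eps <- config$regularization_eps
  priors_by_class <- list()
  for (cl in unique(dataset$prior_class))
    priors_by_class[[cl]] <- session_priors(cl, config)
  ncomp <- integer(nrow(dataset))
  mu_p <- s_p <- numeric(nrow(dataset))
  for (i in seq_len(nrow(dataset))) {
    sp <- priors_by_class[[dataset$prior_class[i]]][[dataset$prior_id[i]]]
    ncomp[i] <- length(sp$mixture$weights)
    if (ncomp[i] == 1L) { mu_p[i] <- dataset$location[i]; s_p[i] <- sp$mixture$sds }
  }
  gaussian <- ncomp == 1L
  dist_ratio <- config$cue_dist_long / config$cue_dist_short
  gh <- gh_normal(config$gh_order)
  mix_rows <- which(!gaussian)
  g_idx <- which(gaussian)
  # 0/1 masks over the Gaussian-prior trials: session and cue level
  tr_g <- as.numeric(dataset$session[g_idx] == "training")
  sh_g <- as.numeric(dataset$cue_level[g_idx] == "short")
  te_g <- 1 - tr_g; lo_g <- 1 - sh_g
  mu <- mu_p[g_idx]; sp0 <- s_p[g_idx]
  cg <- dataset$cue_x[g_idx]; rg <- dataset$response_x[g_idx]
  r_all <- dataset$response_x
  dmc <- cg - mu
  dmr <- rg - mu
  inv_sqrt2pi <- 1 / sqrt(2 * pi)

  function(params) {
    pt <- numeric(nrow(dataset))
    if (length(g_idx)) {
      ratio <- params[["lik_sd_long_train"]] / params[["lik_sd_short_train"]]
      sl <- tr_g * (sh_g * params[["lik_sd_short_train"]] +
                      lo_g * params[["lik_sd_long_train"]]) +
            te_g * (sh_g * params[["lik_sd_short_test"]] +
                      lo_g * params[["lik_sd_short_test"]] * ratio)
      ss2 <- if (spec$S) {
        base <- tr_g * params[["cue_est_sd_train"]] + te_g * params[["cue_est_sd_test"]]
        (base * (sh_g + lo_g * dist_ratio))^2
      } else 0
      kinv <- switch(spec$decision,
                     BDT = 0, PPM = 1,
                     SPK = tr_g / params[["kappa_train"]] + te_g / params[["kappa_test"]],
                     PSA = tr_g / params[["psa_k_train"]] + te_g / params[["psa_k_test"]])
      lam <- if (spec$L) tr_g * params[["lapse_train"]] + te_g * params[["lapse_test"]]
             else 0
      mtr2 <- params[["motor_sd"]]^2
      lik2 <- sl^2 + ss2
      if (spec$P) {
        eta <- tr_g * params[["weber_prior_train"]] + te_g * params[["weber_prior_test"]]
        dens <- 0
        for (k in seq_along(gh$z)) {
          sp2 <- sp0^2 * exp(2 * eta * gh$z[k])
          w <- sp2 / (sp2 + lik2)
          v <- w^2 * ss2 + sp2 * lik2 / (sp2 + lik2) * kinv + mtr2
          node <- exp(-(dmr - w * dmc)^2 / (2 * v)) / sqrt(v)
          if (spec$L) {
            vl <- sp2 + mtr2
            node <- (1 - lam) * node + lam * exp(-dmr^2 / (2 * vl)) / sqrt(vl)
          }
          dens <- dens + gh$w[k] * node
        }
        pt[g_idx] <- log(dens * inv_sqrt2pi + eps)
      } else {
        sp2 <- sp0^2
        w <- sp2 / (sp2 + lik2)
        v <- w^2 * ss2 + sp2 * lik2 / (sp2 + lik2) * kinv + mtr2
        dens <- exp(-(dmr - w * dmc)^2 / (2 * v)) / sqrt(v)
        if (spec$L) {
          vl <- sp2 + mtr2
          dens <- (1 - lam) * dens + lam * exp(-dmr^2 / (2 * vl)) / sqrt(vl)
        }
        pt[g_idx] <- log(dens * inv_sqrt2pi + eps)
      }
    }
    for (i in mix_rows) {
      d <- response_density(spec, params, dataset[i, ], config, r = r_all[i])
      pt[i] <- log(d + eps)
    }
    structure(sum(pt), per_trial = pt)
  }
}
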