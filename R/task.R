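#' Task configuration
#'
#' Constants of the target-estimation task: two cue reliability levels, a
#' 100-dot discretized prior shown on each trial, the success window, and
#' descriptor tables for the three session classes of priors (Gaussian,
#' unimodal, bimodal). Values that the published task defines are used
#' directly (8 Gaussian priors with SDs 0.04-0.18 screen units, 100 dots,
#' 16 conditions per session); remaining constants are package defaults in
#' the same units.
#'
#' @param ... Named overrides of the default fields; unknown names are an
#'   error.
#' @return A validated list of class `"priorcue_config"`.
#' @export
priorcue_config <- function(...) {
  cfg <- list(
    n_targets = 100L,
    sigma_low = 0.06,           # true cue sd, short-distance (low-noise) cues
    sigma_high = 0.14,          # true cue sd, long-distance (high-noise) cues
    cue_dist_short = 6,         # cue distance from the target line, cm
    cue_dist_long = 14,
    window = 2 * 1.25 / 30,     # success window = cursor diameter, screen units
    loss_sd = NULL,             # NULL -> least-squares fit to the square well
    gaussian_sd_range = c(0.04, 0.18),
    unimodal_sd = 0.11,         # total SD of unimodal priors (synthetic default)
    bimodal_sd = 0.11,          # total SD of bimodal priors (synthetic default)
    component_sd_floor = 0.015, # lower bound on unimodal component SDs
    # Synthetic descriptor tables (the published per-prior values are not
    # machine-readable); skew/kurtosis pairs respect the unimodal feasibility
    # region, bimodal separations are in units of the total SD.
    unimodal_table = data.frame(
      skewness    = c(1.3, 1.1, 0.9, 0.0, 0.7, 0.5, 0.25, 0.0),
      ex_kurtosis = c(2.8, 1.9, 1.2, -0.85, 0.7, 0.35, 0.1, 0.0),
      platykurtic = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE, FALSE, FALSE)),
    bimodal_table = data.frame(
      separation = c(1.95, 1.95, 1.8, 1.8, 1.6, 1.6, 1.45, 0.0),
      weight     = c(0.5, 0.3, 0.5, 0.3, 0.5, 0.3, 0.5, 0.5)),
    repetitions = 36L,
    screen = c(0, 1),
    regularization_eps = stats::dnorm(5),
    gh_order = 20L,
    kl_threshold = 0.02)
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), names(cfg))
    if (length(bad)) stop("unknown config field(s): ", paste(bad, collapse = ", "))
    cfg[names(over)] <- over
  }
  validate_config(cfg)
  if (is.null(cfg$loss_sd)) cfg$loss_sd <- best_loss_sd(cfg$window)
  cfg$loss <- loss_model(cfg$window, cfg$loss_sd)
  class(cfg) <- "priorcue_config"
  cfg
}

validate_config <- function(cfg) {
  pos <- c("sigma_low", "sigma_high", "cue_dist_short", "cue_dist_long",
           "window", "unimodal_sd", "bimodal_sd", "component_sd_floor")
  for (f in pos)
    if (!is.numeric(cfg[[f]]) || cfg[[f]] <= 0)
      stop("config field '", f, "' must be a positive number")
  if (!is.null(cfg$loss_sd) && cfg$loss_sd <= 0) stop("config field 'loss_sd' must be positive")
  if (cfg$n_targets < 1) stop("n_targets must be >= 1")
  if (cfg$repetitions < 1) stop("repetitions must be >= 1")
  if (nrow(cfg$unimodal_table) != 8L || nrow(cfg$bimodal_table) != 8L)
    stop("prior descriptor tables must have 8 rows")
  invisible(cfg)
}

#' Prior specification
#'
#' A point in one of the three session classes: the canonical (zero-mean)
#' mixture plus bookkeeping. The realized trial prior is the canonical
#' mixture shifted to `location` and mirrored when `flipped`.
#'
#' @param prior_class `"gaussian"`, `"unimodal"` or `"bimodal"`.
#' @param prior_id Integer 1-8.
#' @param mixture Canonical zero-mean [gm()].
#' @return An object of class `"prior_spec"`.
#' @export
prior_spec <- function(prior_class, prior_id, mixture) {
  stopifnot(prior_class %in% c("gaussian", "unimodal", "bimodal"))
  if (abs(gm_mean(mixture)) > 1e-8)
    stop("canonical prior mixture must have mean 0")
  mo <- gm_moments(mixture)
  structure(list(prior_class = prior_class, prior_id = as.integer(prior_id),
                 mixture = mixture,
                 asymmetric = abs(mo[["skewness"]]) > 1e-8),
            class = "prior_spec")
}

#' Realize a prior on the screen
#'
#' @param spec A [prior_spec()].
#' @param location Trial prior mean, screen units.
#' @param flipped Mirror the canonical shape about its mean?
#' @return A [gm()] in absolute screen coordinates.
#' @export
realize_prior <- function(spec, location, flipped = FALSE) {
  gm_affine(spec$mixture, shift = location, scale = if (flipped) -1 else 1)
}

#' The eight Gaussian session priors
#'
#' Zero-mean Gaussians with SDs evenly spaced between the ends of
#' `gaussian_sd_range` (0.04 to 0.18 screen units by default).
#'
#' @param config A [priorcue_config()].
#' @return List of 8 [prior_spec()] objects.
#' @export
make_gaussian_priors <- function(config = priorcue_config()) {
  sds <- seq(config$gaussian_sd_range[1], config$gaussian_sd_range[2], length.out = 8)
  lapply(1:8, function(i) prior_spec("gaussian", i, gm(1, 0, sds[i])))
}

#' Construct a bimodal prior
#'
#' Mixture of two equal-variance Gaussians with mean zero, the requested
#' total SD, peak separation and relative weight. `separation = 0` collapses
#' to a single Gaussian.
#'
#' @param separation Distance between the component means, screen units.
#' @param relative_weight Weight of the right component, in (0, 1).
#' @param total_sd Total SD of the mixture.
#' @param prior_id Identifier stored on the spec.
#' @return A [prior_spec()].
#' @export
make_bimodal_prior <- function(separation, relative_weight, total_sd, prior_id = 1L) {
  if (separation < 0) stop("separation must be >= 0")
  if (relative_weight <= 0 || relative_weight >= 1)
    stop("relative_weight must lie strictly in (0, 1)")
  if (separation == 0)
    return(prior_spec("bimodal", prior_id, gm(1, 0, total_sd)))
  r <- relative_weight
  vc <- total_sd^2 - r * (1 - r) * separation^2
  if (vc <= 0)
    stop("infeasible bimodal prior: separation too large for total_sd")
  mix <- gm(c(1 - r, r), c(-r * separation, (1 - r) * separation), rep(sqrt(vc), 2))
  prior_spec("bimodal", prior_id, mix)
}

#' Construct a unimodal prior with given skewness and kurtosis
#'
#' Two-Gaussian mixture matching the first four central moments
#' (mean 0, `total_sd`, `target_skewness`, `target_kurtosis`) that locally
#' maximizes differential entropy, subject to a lower bound on the
#' component SDs. The moment system leaves one degree of freedom (the
#' component weight), over which the entropy is maximized numerically.
#'
#' @param target_skewness Skewness of the mixture.
#' @param target_kurtosis Excess kurtosis of the mixture.
#' @param total_sd Total SD, screen units.
#' @param sd_floor Lower bound on component SDs, screen units.
#' @param prior_id Identifier stored on the spec.
#' @return A [prior_spec()]; errors when no feasible mixture exists.
#' @export
make_unimodal_prior <- function(target_skewness, target_kurtosis, total_sd,
                                sd_floor = 0.015, prior_id = 1L) {
  if (target_skewness == 0 && target_kurtosis == 0)
    return(prior_spec("unimodal", prior_id, gm(1, 0, total_sd)))
  floor_std <- sd_floor / total_sd
  sol <- entropy_max_two_gaussian(target_skewness, target_kurtosis, floor_std)
  if (is.null(sol))
    stop("infeasible unimodal prior: no two-Gaussian mixture matches ",
         "(skewness, kurtosis) = (", target_skewness, ", ", target_kurtosis,
         ") with the component-SD floor")
  mix <- gm_affine(sol, scale = total_sd)
  prior_spec("unimodal", prior_id, mix)
}

# Standardized (mean 0, var 1) two-Gaussian mixture with given skewness and
# excess kurtosis, maximizing differential entropy over the one free
# parameter (component weight w). Moment equations are solved for
# (a, v1, v2) at fixed w; b = -w a / (1 - w).
entropy_max_two_gaussian <- function(skew, kurt, floor_std, n_w = 25L) {
  best <- NULL; best_ent <- -Inf
  for (w in seq(0.04, 0.96, length.out = n_w)) {
    sol <- solve_two_gaussian_moments(w, skew, kurt)
    if (is.null(sol)) next
    if (any(sol$sds < floor_std)) next
    ent <- gm_entropy(sol)
    if (ent > best_ent) { best_ent <- ent; best <- sol }
  }
  if (is.null(best)) return(NULL)
  # local refinement of the weight around the grid optimum
  w0 <- best$weights[1]
  ref <- stats::optimize(function(w) {
    sol <- solve_two_gaussian_moments(w, skew, kurt)
    if (is.null(sol) || any(sol$sds < floor_std)) return(1e6)
    -gm_entropy(sol)
  }, c(max(0.02, w0 - 0.1), min(0.98, w0 + 0.1)), tol = 1e-6)
  sol <- solve_two_gaussian_moments(ref$minimum, skew, kurt)
  if (!is.null(sol) && all(sol$sds >= floor_std) && -ref$objective > best_ent)
    best <- sol
  best
}

# Newton solve (via optim on squared residuals, multiple starts) of the
# standardized moment equations for a two-Gaussian mixture at fixed weight.
solve_two_gaussian_moments <- function(w, skew, kurt) {
  q <- 1 - w
  resid <- function(par) {
    a <- par[1]; lv1 <- par[2]; lv2 <- par[3]
    v1 <- exp(lv1); v2 <- exp(lv2)
    b <- -w * a / q
    m2 <- w * (a^2 + v1) + q * (b^2 + v2)
    m3 <- w * (a^3 + 3 * a * v1) + q * (b^3 + 3 * b * v2)
    m4 <- w * (a^4 + 6 * a^2 * v1 + 3 * v1^2) + q * (b^4 + 6 * b^2 * v2 + 3 * v2^2)
    c(m2 - 1, m3 - skew, m4 - (kurt + 3))
  }
  starts <- list(c(0.5, log(0.5), log(0.5)), c(1.0, log(0.3), log(0.8)),
                 c(-0.8, log(0.8), log(0.3)), c(0.2, log(0.9), log(0.2)),
                 c(1.5, log(0.1), log(0.6)), c(-1.2, log(0.6), log(0.2)))
  for (s in starts) {
    par <- newton_solve(resid, s, tol = 1e-12, maxit = 100L)
    if (is.null(par)) next
    a <- par[1]; v1 <- exp(par[2]); v2 <- exp(par[3])
    b <- -w * a / q
    return(gm(c(w, q), c(a, b), sqrt(c(v1, v2))))
  }
  NULL
}

# Damped Newton iteration with forward-difference Jacobian; NULL on failure.
newton_solve <- function(fn, x0, tol = 1e-12, maxit = 100L) {
  x <- x0
  r <- fn(x)
  if (any(!is.finite(r))) return(NULL)
  for (it in seq_len(maxit)) {
    if (max(abs(r)) < tol) return(x)
    J <- vapply(seq_along(x), function(j) {
      h <- 1e-7 * max(1, abs(x[j]))
      xp <- x; xp[j] <- xp[j] + h
      (fn(xp) - r) / h
    }, numeric(length(r)))
    step <- try(solve(J, r), silent = TRUE)
    if (inherits(step, "try-error") || any(!is.finite(step))) return(NULL)
    lam <- 1
    repeat {
      xn <- x - lam * step
      rn <- fn(xn)
      if (all(is.finite(rn)) && sum(rn^2) < sum(r^2)) break
      lam <- lam / 2
      if (lam < 1e-6) return(NULL)
    }
    x <- xn; r <- rn
  }
  if (max(abs(r)) < tol) x else NULL
}

# Platykurtic prior as an equal-weight mixture of n equally spaced
# equal-variance Gaussians (standardized, then scaled by the caller).
make_platykurtic_prior <- function(ex_kurtosis, total_sd, n = 11L, prior_id = 4L) {
  if (ex_kurtosis >= 0) stop("platykurtic prior needs negative excess kurtosis")
  u <- seq(-1, 1, length.out = n)
  c2 <- mean(u^2); c4 <- mean(u^4)
  # var = c2 a^2 + vc = 1; M4 = c4 a^4 + 6 c2 a^2 vc + 3 vc^2 = kurt + 3
  f <- function(a) {
    vc <- 1 - c2 * a^2
    if (vc <= 0) return(NA_real_)
    c4 * a^4 + 6 * c2 * a^2 * vc + 3 * vc^2 - (ex_kurtosis + 3)
  }
  hi <- sqrt(1 / c2) * 0.999
  root <- stats::uniroot(f, c(1e-6, hi), tol = 1e-12)$root
  vc <- 1 - c2 * root^2
  mix <- gm(rep(1 / n, n), total_sd * root * u, rep(total_sd * sqrt(vc), n))
  prior_spec("unimodal", prior_id, mix)
}

#' Session prior sets
#'
#' The 8 priors of a session class, built from the configured descriptor
#' tables.
#'
#' @param prior_class `"gaussian"`, `"unimodal"` or `"bimodal"`.
#' @param config A [priorcue_config()].
#' @return List of 8 [prior_spec()] objects.
#' @export
session_priors <- function(prior_class, config = priorcue_config()) {
  switch(prior_class,
    gaussian = make_gaussian_priors(config),
    unimodal = lapply(1:8, function(i) {
      tb <- config$unimodal_table[i, ]
      if (isTRUE(tb$platykurtic))
        make_platykurtic_prior(tb$ex_kurtosis, config$unimodal_sd, prior_id = i)
      else
        make_unimodal_prior(tb$skewness, tb$ex_kurtosis, config$unimodal_sd,
                            config$component_sd_floor, prior_id = i)
    }),
    bimodal = lapply(1:8, function(i) {
      tb <- config$bimodal_table[i, ]
      make_bimodal_prior(tb$separation * config$bimodal_sd, tb$weight,
                         config$bimodal_sd, prior_id = i)
    }),
    stop("unknown prior class: ", prior_class))
}

#' Discretize a prior into target dots
#'
#' Positions of the n potential targets: quantiles of the realized prior at
#' the regular cdf levels (i - 1/2)/n, i = 1..n.
#'
#' @param prior A realized prior ([gm()]).
#' @param n Number of dots.
#' @return Sorted numeric vector of length `n`.
#' @export
discretize_prior <- function(prior, n = 100L) {
  if (n < 1) stop("n must be >= 1")
  qgm(((1:n) - 0.5) / n, prior)
}

#' Build a randomized session plan
#'
#' A session crosses the 8 priors of its class with the two cue levels
#' (16 conditions) at `repetitions` trials each, in random order.
#'
#' @param session `"training"` or `"test"`.
#' @param prior_class Session prior class.
#' @param repetitions Trials per condition (36-40 in the task).
#' @param shuffle Randomize trial order?
#' @return Data frame with one row per trial: `session`, `prior_class`,
#'   `prior_id`, `cue_level`.
#' @export
build_session_plan <- function(session, prior_class, repetitions = 36L,
                               shuffle = TRUE) {
  if (repetitions < 36L || repetitions > 40L)
    stop("repetitions must lie in [36, 40]")
  plan <- expand.grid(prior_id = 1:8, cue_level = c("short", "long"),
                      rep = seq_len(repetitions), stringsAsFactors = FALSE)
  plan <- data.frame(session = session, prior_class = prior_class,
                     prior_id = plan$prior_id, cue_level = plan$cue_level,
                     stringsAsFactors = FALSE)
  if (shuffle) plan <- plan[sample.int(nrow(plan)), , drop = FALSE]
  rownames(plan) <- NULL
  plan
}

#' Sample one trial
#'
#' Draws the trial-level latent structure of the task: flip (probability 1/2
#' for asymmetric priors), uniform prior location keeping the 100-dot span
#' inside the screen, a true target uniform over the dots, and a cue normal
#' around the target with the level's true sd.
#'
#' @param condition List or one-row data frame with `session`, `prior_class`,
#'   `prior_id`, `cue_level`.
#' @param priors Prior set for the class (from [session_priors()]).
#' @param config A [priorcue_config()].
#' @return One-row data frame (a trial record).
#' @export
sample_trial <- function(condition, priors, config = priorcue_config(),
                         disc = NULL) {
  spec <- priors[[condition$prior_id]]
  flipped <- spec$asymmetric && stats::runif(1) < 0.5
  qs <- if (!is.null(disc)) {
    disc[[paste0(condition$prior_id, if (flipped) "f" else "u")]]
  } else {
    discretize_prior(gm_affine(spec$mixture, scale = if (flipped) -1 else 1),
                     config$n_targets)
  }
  lo <- config$screen[1] - qs[1]
  hi <- config$screen[2] - qs[length(qs)]
  if (hi < lo) stop("prior span exceeds the screen window")
  location <- stats::runif(1, lo, hi)
  targets <- location + qs
  target_x <- targets[sample.int(config$n_targets, 1)]
  sigma <- cue_sd_for(condition$cue_level, config)
  cue_x <- stats::rnorm(1, target_x, sigma)
  data.frame(session = condition$session, prior_class = condition$prior_class,
             prior_id = spec$prior_id, cue_level = condition$cue_level,
             flipped = flipped, location = location, target_x = target_x,
             cue_x = cue_x,
             cue_distance = if (condition$cue_level == "short")
               config$cue_dist_short else config$cue_dist_long,
             response_x = NA_real_,
             edge_excluded = cue_x < min(targets) || cue_x > max(targets),
             stringsAsFactors = FALSE)
}

cue_sd_for <- function(cue_level, config) {
  ifelse(cue_level == "short", config$sigma_low, config$sigma_high)
}

#' Sample all trials of a session plan
#'
#' @param plan Output of [build_session_plan()].
#' @param priors Matching prior set.
#' @param config A [priorcue_config()].
#' @return Data frame of trial records.
#' @export
sample_session <- function(plan, priors, config = priorcue_config()) {
  # canonical discretizations depend only on (prior_id, flip); cache them
  disc <- list()
  for (id in unique(plan$prior_id)) {
    base <- discretize_prior(priors[[id]]$mixture, config$n_targets)
    disc[[paste0(id, "u")]] <- base
    disc[[paste0(id, "f")]] <- rev(-base)
  }
  rows <- lapply(seq_len(nrow(plan)), function(i)
    sample_trial(plan[i, ], priors, config, disc))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Edge filter
#'
#' TRUE (exclude) when the cue falls strictly outside the closed range of
#' the discretized prior; recomputable from the stored trial columns.
#'
#' @param trial One or more trial records.
#' @param config A [priorcue_config()].
#' @return Logical vector.
#' @export
edge_filter <- function(trial, config = priorcue_config()) {
  vapply(seq_len(nrow(trial)), function(i) {
    tr <- trial[i, ]
    spec <- session_priors(tr$prior_class, config)[[tr$prior_id]]
    canon <- gm_affine(spec$mixture, scale = if (tr$flipped) -1 else 1)
    qs <- discretize_prior(canon, config$n_targets)
    tr$cue_x < tr$location + qs[1] || tr$cue_x > tr$location + qs[length(qs)]
  }, logical(1))
}

#' Non-Gaussian trial filter
#'
#' Keeps a trial for the decision-rule comparison when the
#' Kullback-Leibler non-Gaussianity of the trial's generative posterior
#' (true cue sd) reaches `threshold` nats. Gaussian-class trials are always
#' excluded (their posteriors are exactly Gaussian).
#'
#' @param trial One or more trial records.
#' @param config A [priorcue_config()].
#' @param threshold Threshold in nats.
#' @return Logical vector: TRUE = keep.
#' @export
nongaussian_trial_filter <- function(trial, config = priorcue_config(),
                                     threshold = config$kl_threshold) {
  if (!is.finite(threshold)) return(rep(FALSE, nrow(trial)))
  vapply(seq_len(nrow(trial)), function(i) {
    tr <- trial[i, ]
    spec <- session_priors(tr$prior_class, config)[[tr$prior_id]]
    prior <- realize_prior(spec, tr$location, tr$flipped)
    post <- posterior_update(prior, tr$cue_x, cue_sd_for(tr$cue_level, config))
    as.numeric(kl_nongaussianity(post)) >= threshold
  }, logical(1))
}
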