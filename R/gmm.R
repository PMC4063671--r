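#' One-dimensional Gaussian mixtures
#'
#' `gm()` builds the density object used throughout the package for priors,
#' posteriors, target-choice and response distributions: a finite mixture of
#' univariate Gaussians with weights `weights`, means `means` (screen units)
#' and standard deviations `sds`.
#'
#' @param weights Numeric vector of non-negative mixing weights; must sum to
#'   one (a deviation below `1e-8` is renormalized, anything larger is an
#'   error).
#' @param means Numeric vector of component means, screen units.
#' @param sds Numeric vector of positive component standard deviations.
#' @return An object of class `"gm"`.
#' @examples
#' g <- gm(c(0.5, 0.5), c(-1, 1), c(0.1, 0.1))
#' dgm(0, g)
#' @export
gm <- function(weights, means, sds) {
  weights <- as.numeric(weights); means <- as.numeric(means); sds <- as.numeric(sds)
  n <- length(weights)
  if (n < 1L || length(means) != n || length(sds) != n)
    stop("weights, means and sds must have equal length >= 1")
  if (any(!is.finite(weights)) || any(!is.finite(means)) || any(!is.finite(sds)))
    stop("gm components must be finite")
  if (any(weights < 0)) stop("weights must be non-negative")
  if (any(sds <= 0)) stop("sds must be positive")
  s <- sum(weights)
  if (abs(s - 1) > 1e-8) stop("weights must sum to 1 (got ", format(s), ")")
  if (abs(s - 1) > 1e-12) weights <- weights / s
  structure(list(weights = weights, means = means, sds = sds), class = "gm")
}

#' @export
print.gm <- function(x, ...) {
  cat("Gaussian mixture with", length(x$weights), "component(s)\n")
  print(data.frame(weight = x$weights, mean = x$means, sd = x$sds))
  invisible(x)
}

#' Mixture density, distribution and quantile functions
#'
#' @param x Numeric vector of evaluation points.
#' @param gm A [gm()] object.
#' @param log Return log-density?
#' @return Numeric vector.
#' @export
dgm <- function(x, gm, log = FALSE) {
  d <- vapply(seq_along(gm$weights),
              function(i) gm$weights[i] * stats::dnorm(x, gm$means[i], gm$sds[i]),
              numeric(length(x)))
  out <- if (length(x) == 1L) sum(d) else rowSums(matrix(d, nrow = length(x)))
  if (log) base::log(out) else out
}

#' @rdname dgm
#' @export
pgm <- function(x, gm) {
  p <- vapply(seq_along(gm$weights),
              function(i) gm$weights[i] * stats::pnorm(x, gm$means[i], gm$sds[i]),
              numeric(length(x)))
  if (length(x) == 1L) sum(p) else rowSums(matrix(p, nrow = length(x)))
}

#' @rdname dgm
#' @param q Probabilities in (0, 1).
#' @export
qgm <- function(q, gm) {
  if (any(q <= 0 | q >= 1)) stop("quantile probabilities must lie strictly in (0, 1)")
  lo <- min(gm$means + stats::qnorm(min(q) / length(gm$weights)) * gm$sds) - 1
  hi <- max(gm$means + stats::qnorm(1 - (1 - max(q)) / length(gm$weights)) * gm$sds) + 1
  vapply(q, function(qi) {
    x <- stats::uniroot(function(z) pgm(z, gm) - qi, c(lo, hi),
                        tol = .Machine$double.eps^0.75, extendInt = "upX")$root
    # Newton polish to drive |cdf(x) - q| below 1e-12
    for (it in 1:8) {
      err <- pgm(x, gm) - qi
      if (abs(err) <= 1e-13) break
      dens <- dgm(x, gm)
      if (dens <= 0) break
      x <- x - err / dens
    }
    x
  }, numeric(1))
}

#' Evaluate a mixture in pdf, cdf or quantile mode
#'
#' Thin dispatcher over [dgm()], [pgm()] and [qgm()] kept as a single entry
#' point for generic callers.
#'
#' @param gm A [gm()] object.
#' @param x Evaluation point(s): a position for `"pdf"`/`"cdf"`, a
#'   probability in (0, 1) for `"quantile"`.
#' @param mode One of `"pdf"`, `"cdf"`, `"quantile"`.
#' @export
gm_eval <- function(gm, x, mode = c("pdf", "cdf", "quantile")) {
  switch(match.arg(mode), pdf = dgm(x, gm), cdf = pgm(x, gm), quantile = qgm(x, gm))
}

#' Exact central moments of a Gaussian mixture
#'
#' Closed-form mean, variance, skewness and excess kurtosis.
#'
#' @param gm A [gm()] object.
#' @return Named numeric vector `(mean, variance, skewness, ex_kurtosis)`.
#' @export
gm_moments <- function(gm) {
  w <- gm$weights; m <- gm$means; v <- gm$sds^2
  mu <- sum(w * m)
  d <- m - mu
  M2 <- sum(w * (d^2 + v))
  M3 <- sum(w * (d^3 + 3 * d * v))
  M4 <- sum(w * (d^4 + 6 * d^2 * v + 3 * v^2))
  c(mean = mu, variance = M2,
    skewness = if (M2 > 0) M3 / M2^1.5 else 0,
    ex_kurtosis = if (M2 > 0) M4 / M2^2 - 3 else 0)
}

#' Differential entropy of a mixture (quadrature estimate)
#'
#' @param gm A [gm()] object.
#' @param step Grid step relative to the smallest component sd.
#' @return Entropy in nats.
#' @export
gm_entropy <- function(gm, step = 0.02) {
  g <- gm_grid(gm, step = step * min(gm$sds))
  p <- dgm(g, gm)
  keep <- p > 0
  -sum(p[keep] * log(p[keep])) * (g[2] - g[1])
}

# Evaluation grid covering all components out to `spread` total sds.
gm_grid <- function(gm, step = 5e-4, spread = 6) {
  smax <- max(gm$sds)
  lo <- min(gm$means) - spread * smax
  hi <- max(gm$means) + spread * smax
  seq(lo, hi, by = step)
}

# Affine image of a mixture: x -> scale * x + shift (scale = -1 mirrors).
gm_affine <- function(gm, shift = 0, scale = 1) {
  gm(gm$weights, scale * gm$means + shift, abs(scale) * gm$sds)
}

gm_mean <- function(gm) sum(gm$weights * gm$means)

gm_var <- function(gm) {
  mu <- gm_mean(gm)
  sum(gm$weights * ((gm$means - mu)^2 + gm$sds^2))
}

# Random draws from a mixture.
gm_sample <- function(n, gm) {
  k <- sample.int(length(gm$weights), n, replace = TRUE, prob = gm$weights)
  stats::rnorm(n, gm$means[k], gm$sds[k])
}

#' Inverted-Gaussian loss model
#'
#' The task scores a trial as a success when the true target falls inside a
#' window of size `window` (the cursor diameter) centred on the response.
#' For decision making the hit-or-miss square well is replaced by a smooth
#' inverted-Gaussian loss of scale `loss_sd`; by default `loss_sd` is the
#' least-squares best Gaussian approximation to the square well of the
#' configured window, computed once by a one-dimensional fit.
#'
#' @param window Success window (cursor diameter), screen units. The default
#'   derives from a 1.25 cm cursor radius with 0.01 screen units = 3 mm.
#' @param loss_sd Scale of the inverted-Gaussian loss; `NULL` fits it to
#'   `window`.
#' @return An object of class `"loss_model"` with fields `window`, `loss_sd`.
#' @export
loss_model <- function(window = 2 * 1.25 / 30, loss_sd = NULL) {
  if (window <= 0) stop("window must be positive")
  if (is.null(loss_sd)) loss_sd <- best_loss_sd(window)
  if (loss_sd <= 0) stop("loss_sd must be positive")
  structure(list(window = window, loss_sd = loss_sd), class = "loss_model")
}

# Least-squares inverted-Gaussian approximation to the square well:
# minimize over s of int (1[|x| <= w/2] - exp(-x^2 / 2 s^2))^2 dx.
best_loss_sd <- function(window) {
  h <- window / 2
  obj <- function(s) {
    stats::integrate(function(x) (as.numeric(abs(x) <= h) - exp(-x^2 / (2 * s^2)))^2,
                     -6 * h, 6 * h, rel.tol = 1e-10)$value
  }
  stats::optimize(obj, c(window / 20, 2 * window))$minimum
}

#' Posterior for a mixture prior and Gaussian likelihood
#'
#' Exact product-of-Gaussians update: for a prior that is a mixture of
#' Gaussians and a Gaussian likelihood centred on the cue with sd `lik_sd`,
#' the posterior is again a mixture whose component weights, means and
#' variances have closed form. For a single-Gaussian prior the posterior
#' mean reduces to the familiar reliability-weighted linear combination with
#' cue weight w = sigma_p^2 / (sigma_p^2 + lik_sd^2).
#'
#' @param prior A [gm()] object.
#' @param cue_x Cue position, screen units.
#' @param lik_sd Likelihood standard deviation (> 0).
#' @return An object of class `c("posterior_gm")`: list with `base` (the
#'   posterior [gm()]) and `log_norm`, the log normalization constant of
#'   prior x likelihood.
#' @export
posterior_update <- function(prior, cue_x, lik_sd) {
  if (lik_sd <= 0) stop("lik_sd must be positive")
  t2 <- lik_sd^2
  s2 <- prior$sds^2
  lZ <- log(prior$weights) + stats::dnorm(cue_x, prior$means, sqrt(s2 + t2), log = TRUE)
  M <- max(lZ)
  log_norm <- M + log(sum(exp(lZ - M)))
  w <- exp(lZ - log_norm)
  post_m <- (prior$means * t2 + cue_x * s2) / (s2 + t2)
  post_v <- s2 * t2 / (s2 + t2)
  structure(list(base = gm(w, post_m, sqrt(post_v)), log_norm = log_norm),
            class = "posterior_gm")
}

as_gm <- function(x) {
  if (inherits(x, "posterior_gm")) x$base
  else if (inherits(x, "gm")) x
  else stop("expected a 'gm' or 'posterior_gm' object")
}

#' Expected inverted-Gaussian loss of an action
#'
#' For a mixture posterior the expectation of the inverted-Gaussian loss has
#' closed form: a negative mixture of Gaussians in the action, with each
#' component variance inflated by `loss_sd^2`.
#'
#' @param post A posterior ([posterior_update()]) or plain [gm()].
#' @param action Numeric vector of candidate actions.
#' @param loss A [loss_model()].
#' @return Expected loss (negative), vectorized over `action`.
#' @export
expected_loss <- function(post, action, loss) {
  g <- as_gm(post)
  sl2 <- loss$loss_sd^2
  val <- vapply(action, function(a)
    sum(g$weights * stats::dnorm(a, g$means, sqrt(g$sds^2 + sl2))), numeric(1))
  -sqrt(2 * pi * sl2) * val
}

# Global mode of a Gaussian mixture with optional variance inflation,
# by fixed-point (mean-shift) iteration started from every component mean.
# Exact ties in density are broken to the smallest coordinate.
gm_mode <- function(g, extra_var = 0, tol = 1e-10, maxit = 1000L) {
  v <- g$sds^2 + extra_var
  w <- g$weights; m <- g$means
  if (length(w) == 1L) return(m)
  dens <- function(x) sum(w * stats::dnorm(x, m, sqrt(v)))
  pts <- numeric(0)
  for (x0 in m) {
    x <- x0
    converged <- FALSE
    for (it in seq_len(maxit)) {
      gi <- w * stats::dnorm(x, m, sqrt(v)) / v
      xn <- sum(gi * m) / sum(gi)
      if (abs(xn - x) <= tol) { x <- xn; converged <- TRUE; break }
      x <- xn
    }
    if (!converged)
      stop(structure(class = c("priorcue_mode_error", "error", "condition"),
                     list(message = paste0("mode search did not converge; best iterate ",
                                           format(x)),
                          call = sys.call(-1), best = x)))
    pts <- c(pts, x)
  }
  f <- vapply(pts, dens, numeric(1))
  best <- f >= max(f) - 1e-12 * max(f)
  min(pts[best])
}

#' Optimal target under the inverted-Gaussian loss
#'
#' Returns the action minimizing [expected_loss()], i.e. the global mode of
#' the loss-smoothed posterior mixture, found by fixed-point iteration
#' started from every component mean. For a single-Gaussian posterior this
#' is its mean. Exact ties are broken to the smaller coordinate.
#'
#' @inheritParams expected_loss
#' @param tol Fixed-point convergence tolerance.
#' @param maxit Maximum iterations per start.
#' @return The optimal action (scalar).
#' @export
optimal_target <- function(post, loss, tol = 1e-10, maxit = 1000L) {
  gm_mode(as_gm(post), extra_var = loss$loss_sd^2, tol = tol, maxit = maxit)
}

#' Power-of-posterior target-choice density
#'
#' Density proportional to `posterior(x)^kappa`, the stochastic-posterior
#' decision rule: `kappa = 1` is posterior matching, large `kappa`
#' concentrates on the MAP. Closed form (a single Gaussian with variance
#' divided by `kappa`) when the posterior has one component; otherwise a
#' normalized grid density.
#'
#' @inheritParams expected_loss
#' @param kappa Positive power.
#' @param grid Optional evaluation grid.
#' @return A `grid_density` object (see [ddens()]).
#' @export
power_density <- function(post, kappa, grid = NULL) {
  if (kappa <= 0) stop("kappa must be positive")
  g <- as_gm(post)
  if (kappa == 1) return(grid_density_from_gm(g, grid))
  if (length(g$weights) == 1L)
    return(grid_density_from_gm(gm(1, g$means, g$sds / sqrt(kappa)), grid))
  if (is.null(grid)) grid <- gm_grid(g)
  lp <- dgm(grid, g, log = TRUE) * kappa
  lp <- lp - max(lp)
  p <- exp(lp)
  p <- p / (sum(p) * (grid[2] - grid[1]))
  grid_density(grid, p)
}

# --- grid densities -------------------------------------------------------
# Target-choice and response distributions that have no mixture form are
# carried as normalized densities on a uniform grid.

grid_density <- function(x, pdf, mix = NULL) {
  structure(list(x = x, pdf = pdf, mix = mix), class = "grid_density")
}

grid_density_from_gm <- function(g, grid = NULL) {
  if (is.null(grid)) grid <- gm_grid(g)
  grid_density(grid, dgm(grid, g), mix = g)
}

#' Evaluate a grid density
#'
#' Analytic when the object wraps an exact mixture, linear interpolation
#' otherwise (zero outside the grid).
#'
#' @param x Evaluation points.
#' @param dens A `grid_density` object.
#' @export
ddens <- function(x, dens) {
  if (!is.null(dens$mix)) return(dgm(x, dens$mix))
  stats::approx(dens$x, dens$pdf, xout = x, yleft = 0, yright = 0)$y
}

# Draw from a grid density by inverse-cdf on the grid.
dens_sample <- function(n, dens) {
  if (!is.null(dens$mix)) return(gm_sample(n, dens$mix))
  dx <- dens$x[2] - dens$x[1]
  cw <- cumsum(dens$pdf) * dx
  cw <- cw / cw[length(cw)]
  u <- stats::runif(n)
  idx <- findInterval(u, cw) + 1L
  idx <- pmin(idx, length(dens$x))
  lo <- c(0, cw)[idx]
  hi <- cw[idx]
  frac <- ifelse(hi > lo, (u - lo) / (hi - lo), 0.5)
  dens$x[idx] - dx / 2 + frac * dx
}

dens_mean_var <- function(dens) {
  if (!is.null(dens$mix)) {
    mo <- gm_moments(dens$mix)
    return(c(mo[["mean"]], mo[["variance"]]))
  }
  dx <- dens$x[2] - dens$x[1]
  m <- sum(dens$x * dens$pdf) * dx
  v <- sum((dens$x - m)^2 * dens$pdf) * dx
  c(m, v)
}

#' Laplace approximation of a mixture posterior
#'
#' Single Gaussian centred on the global posterior mode with variance equal
#' to minus the inverse second derivative of the log posterior at the mode.
#'
#' @inheritParams expected_loss
#' @return A single-component [gm()].
#' @export
laplace_approx <- function(post) {
  g <- as_gm(post)
  mode <- gm_mode(g)
  h <- log_dgm_hess(mode, g)
  if (h >= 0)
    stop("degenerate posterior: non-negative log-density curvature at the mode")
  gm(1, mode, sqrt(-1 / h))
}

# Analytic second derivative of log mixture density.
log_dgm_hess <- function(x, g) {
  v <- g$sds^2
  phi <- g$weights * stats::dnorm(x, g$means, g$sds)
  f <- sum(phi)
  f1 <- sum(phi * (g$means - x) / v)
  f2 <- sum(phi * (((g$means - x)^2 / v - 1) / v))
  (f2 * f - f1^2) / f^2
}

#' Moment-matched Gaussian (mean/variance) approximation
#'
#' @inheritParams expected_loss
#' @return A single-component [gm()].
#' @export
mv_approx <- function(post) {
  g <- as_gm(post)
  mo <- gm_moments(g)
  gm(1, mo[["mean"]], sqrt(mo[["variance"]]))
}

#' Density of the mean of k posterior draws
#'
#' Target-choice density of the sample-averaging decision rule. For integer
#' `k` (up to `max_exact`) the density is computed exactly through the
#' k-fold multinomial expansion of the mixture; non-integer `k` interpolates
#' linearly between the densities at the neighbouring integers; beyond
#' `max_exact` the central-limit Gaussian N(mean, var / k) is used. For a
#' single-component posterior the closed Gaussian form is exact for every
#' real `k` and is used directly.
#'
#' @inheritParams expected_loss
#' @param k Number of averaged draws, a real number >= 1.
#' @param grid Optional evaluation grid.
#' @param max_exact Largest integer k expanded exactly (the expansion grows
#'   combinatorially).
#' @return A `grid_density` object.
#' @export
sample_average_density <- function(post, k, grid = NULL, max_exact = 8L) {
  if (k < 1) stop("k must be >= 1")
  g <- as_gm(post)
  if (length(g$weights) == 1L)
    return(grid_density_from_gm(gm(1, g$means, g$sds / sqrt(k)), grid))
  mo <- gm_moments(g)
  if (k > max_exact)
    return(grid_density_from_gm(gm(1, mo[["mean"]], sqrt(mo[["variance"]] / k)), grid))
  if (abs(k - round(k)) < 1e-12)
    return(grid_density_from_gm(average_k_mixture(g, as.integer(round(k))), grid))
  k0 <- floor(k); k1 <- k0 + 1
  d0 <- average_k_mixture(g, as.integer(k0))
  d1 <- if (k1 > max_exact) gm(1, mo[["mean"]], sqrt(mo[["variance"]] / k1))
        else average_k_mixture(g, as.integer(k1))
  if (is.null(grid)) grid <- gm_grid(g)
  frac <- k - k0
  grid_density(grid, (1 - frac) * dgm(grid, d0) + frac * dgm(grid, d1))
}

# Exact mixture for the mean of k iid draws from mixture g: enumerate the
# multinomial component counts.
average_k_mixture <- function(g, k) {
  M <- length(g$weights)
  if (M == 1L) return(gm(1, g$means, g$sds / sqrt(k)))
  counts <- compositions_of(k, M)
  w <- apply(counts, 1, function(n)
    exp(lgamma(k + 1) - sum(lgamma(n + 1)) + sum(n * log(g$weights))))
  m <- as.numeric(counts %*% g$means) / k
  v <- as.numeric(counts %*% (g$sds^2)) / k^2
  gm(w / sum(w), m, sqrt(v))
}

# All vectors of M non-negative integers summing to k.
compositions_of <- function(k, M) {
  if (M == 1L) return(matrix(k, 1, 1))
  out <- NULL
  for (i in 0:k) {
    sub <- compositions_of(k - i, M - 1L)
    out <- rbind(out, cbind(i, sub))
  }
  unname(out)
}

#' Success probability of a response
#'
#' Probability, under the generative posterior of the task, that the true
#' target lies within the success window centred on the response. Closed
#' form via Gaussian cdf differences over the posterior components.
#'
#' @param prior Generative trial prior, a [gm()].
#' @param cue_x Cue position.
#' @param cue_sd True (generative) cue noise sd.
#' @param response Response position(s).
#' @param loss A [loss_model()]; only `window` is used.
#' @return Success probability, vectorized over `response`.
#' @export
success_probability <- function(prior, cue_x, cue_sd, response, loss) {
  post <- posterior_update(prior, cue_x, cue_sd)$base
  h <- loss$window / 2
  vapply(response, function(r)
    sum(post$weights * (stats::pnorm((r + h - post$means) / post$sds) -
                        stats::pnorm((r - h - post$means) / post$sds))),
    numeric(1))
}

#' Maximal success probability of a trial
#'
#' Maximizes [success_probability()] over the response: a coarse scan of the
#' closed-form objective over the posterior range followed by local
#' refinement.
#'
#' @inheritParams success_probability
#' @return List with `prob` (the maximum) and `response` (its argmax).
#' @export
max_success_probability <- function(prior, cue_x, cue_sd, loss) {
  post <- posterior_update(prior, cue_x, cue_sd)$base
  grid <- gm_grid(post, step = loss$window / 50)
  p <- success_probability(prior, cue_x, cue_sd, grid, loss)
  i <- which.max(p)
  lo <- grid[max(1L, i - 2L)]; hi <- grid[min(length(grid), i + 2L)]
  opt <- stats::optimize(function(r) success_probability(prior, cue_x, cue_sd, r, loss),
                         c(lo, hi), maximum = TRUE, tol = 1e-10)
  list(prob = opt$objective, response = opt$maximum)
}

#' Per-trial optimality index
#'
#' Success probability of the response divided by the maximal success
#' probability achievable on the trial; equals 1 for an optimal response.
#'
#' @inheritParams success_probability
#' @export
optimality_index <- function(prior, cue_x, cue_sd, response, loss) {
  mx <- max_success_probability(prior, cue_x, cue_sd, loss)
  if (mx$prob <= 0) stop("degenerate trial: maximal success probability is zero")
  success_probability(prior, cue_x, cue_sd, response, loss) / mx$prob
}

#' Non-Gaussianity of a posterior in nats
#'
#' Kullback-Leibler divergence KL(moment-matched Gaussian || posterior),
#' computed by adaptive quadrature. Posteriors at or above `threshold` nats
#' are flagged non-Gaussian; this drives the trial filter used when
#' comparing decision rules that only differ on non-Gaussian posteriors.
#'
#' @inheritParams expected_loss
#' @param threshold Flagging threshold, nats.
#' @return The divergence (>= 0) with attribute `non_gaussian`.
#' @export
kl_nongaussianity <- function(post, threshold = 0.02) {
  g <- as_gm(post)
  if (length(g$weights) == 1L)
    return(structure(0, non_gaussian = FALSE))
  mo <- gm_moments(g)
  mu <- mo[["mean"]]; sd0 <- sqrt(mo[["variance"]])
  f <- function(x) {
    lg <- stats::dnorm(x, mu, sd0, log = TRUE)
    exp(lg) * (lg - dgm(x, g, log = TRUE))
  }
  lo <- min(mu - 10 * sd0, min(g$means) - 8 * max(g$sds))
  hi <- max(mu + 10 * sd0, max(g$means) + 8 * max(g$sds))
  val <- stats::integrate(f, lo, hi, abs.tol = 1e-10, subdivisions = 500L)$value
  if (val < -1e-9) stop("KL quadrature failed (negative divergence ", format(val), ")")
  val <- max(val, 0)
  structure(val, non_gaussian = val >= threshold)
}
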