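#' Random-effects Bayesian model selection
#'
#' Variational hierarchical model selection over a subjects-by-models
#' matrix of log model evidence (here typically `-DIC/2`): subjects and
#' models are treated as random effects, so several observer models may
#' coexist in the population. Iterates the responsibilities
#' `u_nk ∝ exp(log_evidence_nk + digamma(alpha_k) - digamma(sum alpha))`
#' and the Dirichlet counts `alpha_k = alpha0 + sum_n u_nk` to convergence.
#' `model_probs` is the expected probability that a random subject's data
#' were generated by each model; exceedance probabilities are estimated by
#' Monte-Carlo Dirichlet sampling.
#'
#' @param log_evidence Matrix (subjects x models) of log evidence; a
#'   data.frame is accepted.
#' @param alpha0 Symmetric Dirichlet concentration; below 1 encodes the
#'   belief that only a few models are present.
#' @param n_dirichlet_draws Monte-Carlo draws for exceedance probabilities.
#' @param seed Integer seed for the Monte-Carlo step.
#' @param tol,maxit Convergence control for the variational iteration.
#' @return List with `alpha`, `model_probs`, `exceedance_probs`,
#'   `responsibilities`, `n_iter`.
#' @export
bms_fit <- function(log_evidence, alpha0 = 0.3, n_dirichlet_draws = 1e5L,
                    seed = 1L, tol = 1e-8, maxit = 500L) {
  lme <- as.matrix(log_evidence)
  if (any(!is.finite(lme))) stop("log evidence must be finite")
  if (alpha0 <= 0) stop("alpha0 must be positive")
  n <- nrow(lme); K <- ncol(lme)
  alpha <- rep(alpha0, K)
  for (it in seq_len(maxit)) {
    lu <- sweep(lme, 2, digamma(alpha) - digamma(sum(alpha)), `+`)
    lu <- lu - apply(lu, 1, max)
    u <- exp(lu)
    u <- u / rowSums(u)
    alpha_new <- alpha0 + colSums(u)
    if (max(abs(alpha_new - alpha)) < tol) { alpha <- alpha_new; break }
    alpha <- alpha_new
    if (it == maxit) stop("BMS variational iteration did not converge")
  }
  set.seed(seed)
  draws <- matrix(stats::rgamma(n_dirichlet_draws * K,
                                shape = rep(alpha, each = n_dirichlet_draws)),
                  n_dirichlet_draws, K)
  winners <- max.col(draws)
  xp <- tabulate(winners, K) / n_dirichlet_draws
  probs <- alpha / sum(alpha)
  names(probs) <- names(xp) <- names(alpha) <- colnames(lme)
  list(alpha = alpha, model_probs = probs, exceedance_probs = xp,
       responsibilities = u, n_iter = it)
}

#' Aggregate model evidence over factor levels
#'
#' Cumulative evidence for groups of models (e.g. all models sharing a
#' factor level): runs [bms_fit()] on the full table, sums the member
#' model probabilities per level, and computes level exceedance from the
#' same Dirichlet posterior.
#'
#' @inheritParams bms_fit
#' @param factor_partition Named list of model-index (or model-name)
#'   vectors forming a disjoint cover of the columns.
#' @return List with `level_probs`, `exceedance_probs`, `bms`.
#' @export
factor_aggregate <- function(log_evidence, factor_partition, alpha0 = 0.3,
                             n_dirichlet_draws = 1e5L, seed = 1L) {
  lme <- as.matrix(log_evidence)
  idx <- lapply(factor_partition, function(v) {
    if (is.character(v)) match(v, colnames(lme)) else as.integer(v)
  })
  cover <- sort(unlist(idx))
  if (anyNA(cover) || length(cover) != ncol(lme) || any(cover != seq_len(ncol(lme))))
    stop("factor_partition must be a disjoint cover of the models")
  fit <- bms_fit(lme, alpha0, n_dirichlet_draws = 1L, seed = seed)
  level_probs <- vapply(idx, function(ii) sum(fit$model_probs[ii]), numeric(1))
  set.seed(seed)
  K <- ncol(lme)
  draws <- matrix(stats::rgamma(n_dirichlet_draws * K,
                                shape = rep(fit$alpha, each = n_dirichlet_draws)),
                  n_dirichlet_draws, K)
  draws <- draws / rowSums(draws)
  lvl <- vapply(idx, function(ii) rowSums(draws[, ii, drop = FALSE]),
                numeric(n_dirichlet_draws))
  winners <- max.col(lvl)
  xp <- tabulate(winners, length(idx)) / n_dirichlet_draws
  names(xp) <- names(level_probs) <- names(factor_partition)
  list(level_probs = level_probs, exceedance_probs = xp, bms = fit)
}

#' Fixed-effects group DIC comparison
#'
#' Treats all subjects as generated by one common observer model: column
#' sums of the subjects-by-models DIC matrix, differences to the best
#' model, and a conservative significance flag at 10 DIC points.
#'
#' @param dic_matrix Subjects x models matrix of DIC scores.
#' @param threshold Significance threshold on the group DIC difference.
#' @return List with `gdic` (column sums), `delta` (difference to best),
#'   `best`, `significant`.
#' @export
gdic <- function(dic_matrix, threshold = 10) {
  dm <- as.matrix(dic_matrix)
  if (any(!is.finite(dm))) stop("DIC matrix must be finite")
  g <- colSums(dm)
  delta <- g - min(g)
  list(gdic = g, delta = delta, best = names(g)[which.min(g)],
       significant = delta >= threshold)
}

#' Convert DIC scores to log model evidence
#'
#' The DIC approximation to the log marginal likelihood on the deviance
#' scale: `log evidence = -DIC/2`.
#'
#' @param dic_matrix Subjects x models DIC matrix.
#' @export
dic_to_log_evidence <- function(dic_matrix) -as.matrix(dic_matrix) / 2

#' Partition model strings by factor
#'
#' Helper building the [factor_aggregate()] partition for one factor of
#' the model space.
#'
#' @param models Character vector of model strings.
#' @param factor One of `"decision"`, `"ga"`, `"S"`, `"P"`, `"L"`.
#' @return Named list of model-name vectors.
#' @export
partition_by_factor <- function(models, factor = c("decision", "ga", "S", "P", "L")) {
  factor <- match.arg(factor)
  specs <- lapply(models, parse_observer)
  key <- vapply(specs, function(s) switch(factor,
    decision = s$decision, ga = s$ga,
    S = if (s$S) "S" else "no-S",
    P = if (s$P) "P" else "no-P",
    L = if (s$L) "L" else "no-L"), character(1))
  split(models, key)
}
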