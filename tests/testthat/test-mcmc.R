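test_that("parameter priors respect supports and the power-law on kappa", {
  spec <- parse_observer("SPK-P-L")
  th <- default_params(spec)
  expect_true(is.finite(log_prior(spec, th)))
  th_bad <- th; th_bad[["lapse_train"]] <- 1.2
  expect_equal(log_prior(spec, th_bad), -Inf)
  th_eta <- th; th_eta[["weber_prior_test"]] <- 3.5
  expect_true(is.finite(log_prior(spec, th_eta)))
  th_eta[["weber_prior_test"]] <- 4.5
  expect_equal(log_prior(spec, th_eta), -Inf)
  # Uniform(0, 1] on 1/kappa implies p(kappa) proportional to kappa^-2:
  # log-density differences must equal the analytic Jacobian ratio
  th2 <- th; th2[["kappa_train"]] <- 2
  th4 <- th; th4[["kappa_train"]] <- 4
  expect_equal(log_prior(spec, th2) - log_prior(spec, th4), 2 * log(2))
  th_sub1 <- th; th_sub1[["kappa_train"]] <- 0.5
  expect_equal(log_prior(spec, th_sub1), -Inf)
})

test_that("slice sampler reproduces known distributions and is deterministic", {
  run <- slice_sample(function(x) -x[1]^2 / 2,
                      init = c(x = 0.5), n_chains = 2L, burn_in = 100L,
                      n_samples = 5000L, seed = 8L, widths = 1)
  draws <- as.numeric(run$chains)
  expect_lt(abs(mean(draws)), 3 / sqrt(length(draws)) * 1.5)
  expect_lt(abs(stats::sd(draws) - 1), 0.05)
  runif_target <- function(x) if (x[1] > 0 && x[1] < 1) 0 else -Inf
  ru <- slice_sample(runif_target, init = c(u = 0.5), n_chains = 1L,
                     burn_in = 50L, n_samples = 10000L, seed = 9L, widths = 0.5)
  expect_lt(ks_distance(as.numeric(ru$chains), stats::punif), 0.02)
  again <- slice_sample(function(x) -x[1]^2 / 2,
                        init = c(x = 0.5), n_chains = 2L, burn_in = 100L,
                        n_samples = 5000L, seed = 8L, widths = 1)
  expect_identical(run$chains, again$chains)
})

test_that("Gelman-Rubin statistic matches a two-pass hand formula", {
  set.seed(14)
  m <- 3L; n <- 400L
  ch <- array(stats::rnorm(m * n * 2), c(m, n, 2L))
  rh <- gelman_rubin(ch)
  expect_true(all(rh < 1.01))
  for (j in 1:2) {
    x <- ch[, , j]
    W <- mean(apply(x, 1, stats::var))
    B_over_n <- stats::var(rowMeans(x))
    expect_equal(rh[j], sqrt(((n - 1) / n * W + B_over_n) / W),
                 tolerance = 1e-12, ignore_attr = TRUE)
  }
  ch_bad <- ch
  ch_bad[1, , 1] <- ch_bad[1, , 1] - 10
  ch_bad[2, , 1] <- ch_bad[2, , 1] + 10
  expect_gt(gelman_rubin(ch_bad)[1], 1.1)
})

test_that("DIC reduces to the deviance for flat likelihoods and matches conjugate theory", {
  set.seed(15)
  sam <- cbind(a = stats::rnorm(2000))
  flat <- dic(sam, log_liks = rep(-12.5, 2000), log_lik_fn = function(th) -12.5)
  expect_equal(flat$p_d, 0)
  expect_equal(flat$dic, 25)
  # conjugate normal mean: x_i ~ N(theta, 1), theta ~ N(0, 1)
  n <- 20L
  x <- stats::rnorm(n, 0.4)
  tau2 <- 1 / (n + 1); mu_n <- sum(x) / (n + 1)
  theta <- stats::rnorm(20000, mu_n, sqrt(tau2))
  llf <- function(th) sum(stats::dnorm(x, th[[1]], 1, log = TRUE))
  lls <- vapply(theta, function(t) llf(t), numeric(1))
  d <- dic(cbind(theta = theta), lls, llf)
  expect_equal(d$p_d, n * tau2, tolerance = 0.05)
  # trimmed mean of a symmetric sample equals the untrimmed mean
  sym <- c(-3, -1, 0, 1, 3)
  expect_equal(mean(sym, trim = 0.1), mean(sym))
})

test_that("fitting recovers parameters of a simulated observer", {
  spec <- parse_observer("SPK-L")
  th <- default_params(spec)
  sub <- simulate_subject("gaussian", spec, th, seed = 7, config = cfg)
  fit <- fit_observer(spec, sub$data, cfg, seed = 11,
                      budget = list(n_chains = 3L, burn_in = 50L, n_samples = 150L))
  expect_lt(max(fit$rhat), 1.1)
  expect_true(is.finite(fit$dic))
  expect_gt(fit$p_d, 0)
  expect_equal(unname(fit$theta_hat[c("lik_sd_short_train", "motor_sd")]),
               unname(th[c("lik_sd_short_train", "motor_sd")]),
               tolerance = 0.25)
})
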