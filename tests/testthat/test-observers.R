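# A mixture-prior trial in canonical position, used by several blocks.
mixture_trial <- function(prior_class = "bimodal", prior_id = 2L,
                          cue_x = 0.52, cue_level = "short") {
  data.frame(session = "test", prior_class = prior_class, prior_id = prior_id,
             cue_level = cue_level, flipped = FALSE, location = 0.5,
             target_x = 0.5, cue_x = cue_x, cue_distance = 6,
             response_x = NA_real_, edge_excluded = FALSE)
}

gauss_trial <- function(prior_id = 5L, cue_x = 0.56, session = "training",
                        cue_level = "short") {
  data.frame(session = session, prior_class = "gaussian", prior_id = prior_id,
             cue_level = cue_level, flipped = FALSE, location = 0.5,
             target_x = 0.5, cue_x = cue_x, cue_distance = 6,
             response_x = NA_real_, edge_excluded = FALSE)
}

test_that("model strings parse canonically and parameter counts follow sharing rules", {
  expect_equal(param_count("BDT"), 4)
  expect_equal(param_count("SPK"), 6)
  expect_equal(param_count("PPM"), 4)
  expect_equal(param_count("PSA"), 6)
  expect_equal(param_count("SPK-P-L"), 10)
  expect_equal(param_count("SPK-S-P-L"), 12)
  expect_equal(parse_observer("SPK-P-L")$id, "SPK-P-L")
  expect_equal(observer_spec("PPM", ga = "MV", L = TRUE)$id, "PPM-MV-L")
  expect_error(parse_observer("XYZ-P"), "decision")
  expect_error(parse_observer("SPK-MV-LA"), "exclusive")
})

test_that("factor nesting identities hold on response densities", {
  tr <- mixture_trial()
  r <- seq(0.2, 0.8, length.out = 121)
  # SPK with kappa = 1 is posterior matching
  th_spk <- default_params("SPK"); th_spk[c("kappa_train", "kappa_test")] <- 1
  d_spk <- response_density("SPK", th_spk, tr, cfg, r = r)
  d_ppm <- response_density("PPM", default_params("PPM"), tr, cfg, r = r)
  expect_lt(max(abs(d_spk - d_ppm)), 1e-8)
  # PSA with k = 1 is posterior matching
  th_psa <- default_params("PSA"); th_psa[c("psa_k_train", "psa_k_test")] <- 1
  expect_lt(max(abs(response_density("PSA", th_psa, tr, cfg, r = r) - d_ppm)), 1e-8)
  # lapse, prior noise and cue noise collapse in their zero limits
  th_l <- default_params("SPK-L"); th_l[c("lapse_train", "lapse_test")] <- 0
  d_l <- response_density("SPK-L", th_l, tr, cfg, r = r)
  d_0 <- response_density("SPK", default_params("SPK"), tr, cfg, r = r)
  expect_lt(max(abs(d_l - d_0)), 1e-8)
  th_p <- default_params("SPK-P"); th_p[c("weber_prior_train", "weber_prior_test")] <- 1e-8
  expect_lt(max(abs(response_density("SPK-P", th_p, tr, cfg, r = r) - d_0)), 1e-6)
  th_s <- default_params("SPK-S"); th_s[c("cue_est_sd_train", "cue_est_sd_test")] <- 1e-9
  expect_lt(max(abs(response_density("SPK-S", th_s, tr, cfg, r = r) - d_0)), 1e-6)
})

test_that("Gaussian trials make all deterministic variants aim at the posterior mean", {
  tr <- gauss_trial()
  th <- default_params("BDT")
  targets <- vapply(c("none", "MV", "LA"), function(ga) {
    d <- target_choice_density(observer_spec("BDT", ga = ga), th, tr, cfg)
    attr(d, "delta")
  }, numeric(1))
  w <- 0.12^2 / (0.12^2 + th[["lik_sd_short_train"]]^2)
  expect_equal(unname(targets), rep(0.5 + w * 0.06, 3), tolerance = 1e-9)
})

test_that("closed-form Gaussian response matches the numeric path and simulation", {
  for (m in c("BDT", "SPK", "PPM", "SPK-S", "SPK-L")) {
    th <- default_params(m)
    for (tr in list(gauss_trial(), gauss_trial(2L, 0.47, "test", "long"))) {
      cf <- gaussian_closed_form_response(m, th, tr, cfg)
      r <- cf$mean + seq(-3, 3, length.out = 41) * cf$sd
      ref <- stats::dnorm(r, cf$mean, cf$sd)
      if (!is.null(cf$lapse))
        ref <- (1 - cf$lapse) * ref + cf$lapse * stats::dnorm(r, cf$lapse_mean, cf$lapse_sd)
      expect_lt(max(abs(response_density(m, th, tr, cfg, r = r) - ref)), 1e-6)
    }
  }
  # full generative observer simulation vs closed form (SPK-S)
  th <- default_params("SPK-S")
  tr <- gauss_trial()
  cf <- gaussian_closed_form_response("SPK-S", th, tr, cfg)
  set.seed(40)
  n <- 1e6
  w <- 0.12^2 / (0.12^2 + th[["lik_sd_short_train"]]^2 + th[["cue_est_sd_train"]]^2)
  x_m <- stats::rnorm(n, tr$cue_x, th[["cue_est_sd_train"]])
  post_v <- 0.12^2 * (th[["lik_sd_short_train"]]^2 + th[["cue_est_sd_train"]]^2) /
    (0.12^2 + th[["lik_sd_short_train"]]^2 + th[["cue_est_sd_train"]]^2)
  choice <- stats::rnorm(n, 0.5 + w * (x_m - 0.5),
                         sqrt(post_v / th[["kappa_train"]]))
  resp <- stats::rnorm(n, choice, th[["motor_sd"]])
  expect_lt(ks_distance(resp, function(x) stats::pnorm(x, cf$mean, cf$sd)), 0.005)
  # with the true likelihood sd the mean is the optimal linear prediction
  th_true <- th; th_true[["lik_sd_short_train"]] <- cfg$sigma_low
  th_true[["cue_est_sd_train"]] <- 1e-12
  cf2 <- gaussian_closed_form_response("SPK-S", th_true, tr, cfg)
  w_opt <- 0.12^2 / (0.12^2 + cfg$sigma_low^2)
  expect_equal(cf2$mean, 0.5 + w_opt * 0.06, tolerance = 1e-6)
  expect_error(gaussian_closed_form_response("SPK", th, mixture_trial(), cfg),
               "single-Gaussian")
})

test_that("response densities normalize across decision rules and prior classes", {
  r <- seq(-0.2, 1.2, length.out = 401)
  dx <- r[2] - r[1]
  for (m in c("BDT-L", "SPK", "PPM-P", "PSA-L", "SPK-MV-L", "PPM-LA"))
    for (tr in list(gauss_trial(), mixture_trial("bimodal", 1L),
                    mixture_trial("unimodal", 2L, 0.48))) {
      d <- response_density(m, default_params(m), tr, cfg, r = r)
      expect_equal(sum(d) * dx, 1, tolerance = 1e-4,
                   label = paste("mass of", m))
    }
})

test_that("log-likelihood floors single trials and is translation invariant", {
  th <- default_params("SPK-L")
  d0 <- gauss_trial()
  d0$response_x <- 0.62
  empty <- d0[0, ]
  expect_equal(as.numeric(log_likelihood("SPK-L", th, empty, cfg)), 0)
  far <- d0; far$response_x <- 1e9
  eps <- stats::dnorm(5)
  expect_gte(as.numeric(log_likelihood("SPK-L", th, far, cfg)), log(eps))
  expect_equal(as.numeric(log_likelihood("SPK-L", th, far, cfg)), log(eps),
               tolerance = 1e-6)
  # translating the whole trial leaves the likelihood unchanged
  sh <- 0.18
  d1 <- d0
  d1$location <- d1$location + sh; d1$cue_x <- d1$cue_x + sh
  d1$target_x <- d1$target_x + sh; d1$response_x <- d1$response_x + sh
  expect_equal(as.numeric(log_likelihood("SPK-L", th, d1, cfg)),
               as.numeric(log_likelihood("SPK-L", th, d0, cfg)),
               tolerance = 1e-10)
})

test_that("the likelihood is maximized near the generating parameters", {
  spec <- parse_observer("SPK-L")
  th <- default_params(spec)
  sub <- simulate_subject("gaussian", spec, th, seed = 77, config = cfg)
  ll <- make_loglik(spec, sub$data, cfg)
  base <- as.numeric(ll(th))
  for (p in c("lik_sd_short_train", "kappa_train")) {
    for (f in c(0.7, 1.4)) {
      th2 <- th; th2[[p]] <- th[[p]] * f
      expect_lt(as.numeric(ll(th2)), base, label = paste(p, "x", f))
    }
  }
  # motor noise only shows up against large perturbations (it is a small
  # share of the total response variance)
  th_m <- th; th_m[["motor_sd"]] <- th[["motor_sd"]] * 3
  expect_lt(as.numeric(ll(th_m)), base)
})
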