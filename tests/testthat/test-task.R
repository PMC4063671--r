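test_that("Gaussian prior set matches the session design", {
  pr <- make_gaussian_priors(cfg)
  sds <- vapply(pr, function(p) p$mixture$sds, numeric(1))
  expect_length(pr, 8)
  expect_equal(sds[1], 0.04)
  expect_equal(sds[8], 0.18)
  expect_equal(diff(sds), rep(0.02, 7))
  expect_equal(vapply(pr, function(p) gm_moments(p$mixture)[["variance"]],
                      numeric(1)), sds^2)
})

test_that("bimodal construction hits the requested descriptors", {
  p0 <- make_bimodal_prior(0, 0.5, 0.11)
  expect_length(p0$mixture$weights, 1)
  expect_equal(p0$mixture$sds, 0.11)
  p <- make_bimodal_prior(0.15, 0.5, 0.11)
  mo <- gm_moments(p$mixture)
  expect_equal(mo[["skewness"]], 0)
  expect_equal(sqrt(mo[["variance"]]), 0.11, tolerance = 1e-10)
  expect_equal(diff(p$mixture$means), 0.15)
  p2 <- make_bimodal_prior(0.18, 0.3, 0.11)
  mo2 <- gm_moments(p2$mixture)
  expect_equal(mo2[["mean"]], 0, tolerance = 1e-12)
  expect_equal(sqrt(mo2[["variance"]]), 0.11, tolerance = 1e-10)
  expect_error(make_bimodal_prior(0.5, 0.5, 0.11), "infeasible")
})

test_that("unimodal construction matches moments and maximizes entropy", {
  g0 <- make_unimodal_prior(0, 0, 0.11)
  expect_length(g0$mixture$weights, 1)
  p <- make_unimodal_prior(0.9, 1.2, 0.11, sd_floor = 0.015)
  mo <- gm_moments(p$mixture)
  expect_equal(mo[["mean"]], 0, tolerance = 1e-6)
  expect_equal(sqrt(mo[["variance"]]), 0.11, tolerance = 1e-6)
  expect_equal(mo[["skewness"]], 0.9, tolerance = 1e-6)
  expect_equal(mo[["ex_kurtosis"]], 1.2, tolerance = 1e-6)
  # entropy at least that of random feasible moment-matched mixtures
  ent <- gm_entropy(p$mixture)
  set.seed(17)
  alts <- 0L
  for (w in stats::runif(40, 0.05, 0.95)) {
    sol <- priorcue:::solve_two_gaussian_moments(w, 0.9, 1.2)
    if (is.null(sol) || any(sol$sds < 0.015 / 0.11)) next
    alts <- alts + 1L
    expect_gte(ent + 1e-4, gm_entropy(gm_affine(sol, scale = 0.11)))
  }
  expect_gt(alts, 10)
  expect_error(make_unimodal_prior(4, 0.5, 0.11), "infeasible")
})

test_that("platykurtic prior matches moments with 11 components", {
  p <- session_priors("unimodal", cfg)[[4]]
  expect_length(p$mixture$weights, 11)
  mo <- gm_moments(p$mixture)
  expect_equal(sqrt(mo[["variance"]]), cfg$unimodal_sd, tolerance = 1e-9)
  expect_equal(mo[["ex_kurtosis"]], cfg$unimodal_table$ex_kurtosis[4],
               tolerance = 1e-9)
})

test_that("discretization samples the cdf regularly", {
  pr <- realize_prior(make_gaussian_priors(cfg)[[4]], 0.5)
  dots <- discretize_prior(pr, 100)
  expect_length(dots, 100)
  expect_false(is.unsorted(dots))
  # quantile levels (i - 1/2)/100
  expect_equal(pgm(dots, pr), ((1:100) - 0.5) / 100, tolerance = 1e-10)
  # symmetric prior: dot set symmetric about the location
  expect_lt(max(abs((dots - 0.5) + rev(dots - 0.5))), 1e-9)
  # empirical SD of the dots close to the prior SD
  expect_equal(stats::sd(dots), pr$sds, tolerance = 0.02 * pr$sds)
})

test_that("session plans cross 16 conditions at the requested repetitions", {
  plan <- build_session_plan("training", "gaussian", 36, shuffle = FALSE)
  expect_equal(nrow(plan), 576)
  counts <- table(plan$prior_id, plan$cue_level)
  expect_equal(dim(counts), c(8L, 2L))
  expect_true(all(counts == 36))
  expect_error(build_session_plan("training", "gaussian", 20), "36")
  set.seed(2)
  shuffled <- build_session_plan("test", "bimodal", 40)
  expect_equal(nrow(shuffled), 640)
  expect_true(all(table(shuffled$prior_id) == 80))
})

test_that("trial sampling reproduces the generative statistics", {
  priors <- session_priors("bimodal", cfg)
  set.seed(4)
  n <- 4000
  plan <- data.frame(session = "test", prior_class = "bimodal",
                     prior_id = 2L, cue_level = "short",
                     stringsAsFactors = FALSE)[rep(1, n), ]
  trials <- sample_session(plan, priors, cfg)
  # flips at one half for the asymmetric prior
  expect_lt(abs(mean(trials$flipped) - 0.5), 3 * sqrt(0.25 / n))
  # cue noise at the configured level
  err <- trials$cue_x - trials$target_x
  expect_lt(abs(stats::sd(err) - cfg$sigma_low), 0.03 * cfg$sigma_low)
  # all dots within the screen
  expect_true(all(trials$target_x >= 0 & trials$target_x <= 1))
  # targets uniform over the 100 dots: check quantile rank uniformity
  pg <- session_priors("gaussian", cfg)
  plan_g <- data.frame(session = "training", prior_class = "gaussian",
                       prior_id = 8L, cue_level = "long",
                       stringsAsFactors = FALSE)[rep(1, 2000), ]
  tg <- sample_session(plan_g, pg, cfg)
  ranks <- round(pgm(tg$target_x - tg$location, pg[[8]]$mixture) * 100 + 0.5)
  expect_gt(stats::chisq.test(tabulate(ranks, 100))$p.value, 1e-4)
})

test_that("edge filter keeps the closed dot interval and flags outside cues", {
  priors <- session_priors("gaussian", cfg)
  qs <- discretize_prior(priors[[3]]$mixture, cfg$n_targets)
  base <- data.frame(session = "training", prior_class = "gaussian",
                     prior_id = 3L, cue_level = "short", flipped = FALSE,
                     location = 0.5, target_x = 0.5, cue_x = 0.5,
                     cue_distance = 6, response_x = NA_real_,
                     edge_excluded = FALSE)
  at_min <- base; at_min$cue_x <- 0.5 + qs[1]
  outside <- base; outside$cue_x <- 0.5 + qs[1] - 1e-9
  expect_false(edge_filter(base, cfg))
  expect_false(edge_filter(at_min, cfg))
  expect_true(edge_filter(outside, cfg))
})

test_that("exclusion rises with cue noise and priors regenerate identically", {
  priors <- session_priors("gaussian", cfg)
  set.seed(12)
  excl <- vapply(c("short", "long"), function(lev) {
    plan <- data.frame(session = "training", prior_class = "gaussian",
                       prior_id = 2L, cue_level = lev,
                       stringsAsFactors = FALSE)[rep(1, 800), ]
    mean(sample_session(plan, priors, cfg)$edge_excluded)
  }, numeric(1))
  expect_gt(excl[["long"]], excl[["short"]])
  u1 <- session_priors("unimodal", cfg)
  u2 <- session_priors("unimodal", cfg)
  expect_identical(u1, u2)
})

test_that("non-Gaussian trial filter passes bimodal posteriors only", {
  g_trial <- data.frame(session = "training", prior_class = "gaussian",
                        prior_id = 5L, cue_level = "short", flipped = FALSE,
                        location = 0.5, target_x = 0.5, cue_x = 0.52,
                        cue_distance = 6, response_x = NA_real_,
                        edge_excluded = FALSE)
  b_trial <- g_trial
  b_trial$prior_class <- "bimodal"; b_trial$prior_id <- 1L; b_trial$cue_x <- 0.5
  expect_false(nongaussian_trial_filter(g_trial, cfg))
  expect_true(nongaussian_trial_filter(b_trial, cfg))
  expect_false(nongaussian_trial_filter(b_trial, cfg, threshold = Inf))
})
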