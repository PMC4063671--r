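test_that("mixture cdf/quantile are exact inverses and pdf integrates to 1", {
  expect_equal(pgm(0, gm(1, 0, 0.1)), 0.5)
  expect_equal(qgm(0.5, gm(c(0.5, 0.5), c(-1, 1), c(0.1, 0.1))), 0, tolerance = 1e-9)
  expect_error(qgm(0, gm(1, 0, 1)), "strictly")
  set.seed(11)
  g <- random_mixture(3)
  x <- stats::runif(100, -0.4, 0.4)
  expect_lt(max(abs(qgm(pgm(x, g), g) - x)), 1e-9)
  q <- stats::runif(20, 1e-4, 1 - 1e-4)
  expect_lt(max(abs(pgm(qgm(q, g), g) - q)), 1e-12)
  grid <- gm_grid(g)
  expect_equal(sum(dgm(grid, g)) * (grid[2] - grid[1]), 1, tolerance = 1e-6)
  expect_equal(gm_eval(g, 0.1, "cdf"), pgm(0.1, g))
})

test_that("closed-form moments match Monte-Carlo estimates", {
  expect_equal(unname(gm_moments(gm(1, 0.3, 0.07))),
               c(0.3, 0.07^2, 0, 0))
  expect_equal(gm_moments(gm(c(0.5, 0.5), c(-0.1, 0.1), c(0.05, 0.05)))[["skewness"]], 0)
  set.seed(7)
  g <- gm(c(0.3, 0.7), c(-0.12, 0.05), c(0.03, 0.09))
  mo <- gm_moments(g)
  s <- gm_sample(1e6, g)
  expect_lt(abs(mo[["mean"]] - mean(s)), 3 * stats::sd(s) / sqrt(1e6))
  expect_lt(abs(mo[["variance"]] - stats::var(s)), 0.01 * mo[["variance"]])
  m3 <- mean((s - mean(s))^3) / stats::sd(s)^3
  expect_lt(abs(mo[["skewness"]] - m3), 0.03)
})

test_that("posterior update is the exact product-of-Gaussians mixture", {
  # equal prior and likelihood sds: cue weight 1/2
  p <- posterior_update(gm(1, 0, 0.06), 0.06, 0.06)
  expect_equal(gm_mean(p$base), 0.03)
  # prior sd 0.18, likelihood sd 0.06: w = 0.0324/0.0360 = 0.9
  p2 <- posterior_update(gm(1, 0, 0.18), 0.1, 0.06)
  expect_equal(gm_mean(p2$base), 0.09)
  # two-component prior: pointwise agreement with quadrature-normalized
  # prior(x) * N(cue | x, sd)
  pr <- gm(c(0.4, 0.6), c(-0.08, 0.06), c(0.04, 0.07))
  cue <- 0.03; sd_l <- 0.05
  post <- posterior_update(pr, cue, sd_l)
  Z <- stats::integrate(function(x) dgm(x, pr) * stats::dnorm(cue, x, sd_l),
                        -1, 1, rel.tol = 1e-12)$value
  xs <- seq(-0.3, 0.3, length.out = 101)
  ref <- dgm(xs, pr) * stats::dnorm(cue, xs, sd_l) / Z
  expect_lt(max(abs(dgm(xs, post$base) - ref)), 1e-8)
  expect_equal(post$log_norm, log(Z), tolerance = 1e-10)
})

test_that("expected loss has the advertised closed form", {
  loss <- cfg$loss
  # Gaussian posterior: minimum at the mean over a dense grid
  post <- posterior_update(gm(1, 0, 0.08), 0.05, 0.08)
  grid <- seq(-0.3, 0.3, by = 1e-3)
  el <- expected_loss(post, grid, loss)
  expect_equal(grid[which.min(el)], gm_mean(post$base), tolerance = 1e-3)
  # closed form equals quadrature of the defining integral
  set.seed(3)
  for (i in 1:5) {
    post <- random_posterior()
    a <- stats::runif(1, -0.1, 0.1)
    num <- stats::integrate(function(x)
      dgm(x, post$base) * (-exp(-(x - a)^2 / (2 * loss$loss_sd^2))),
      -2, 2, rel.tol = 1e-12)$value
    expect_equal(expected_loss(post, a, loss), num, tolerance = 1e-8)
  }
  # very wide loss flattens the landscape
  flat <- expected_loss(post, grid, loss_model(loss$window, loss_sd = 1e3))
  expect_lt(diff(range(flat)), 1e-6)
})

test_that("optimal target minimizes expected loss globally", {
  loss <- cfg$loss
  expect_equal(optimal_target(posterior_update(gm(1, 0.2, 0.05), 0.2, 0.05), loss), 0.2)
  # symmetric equal bimodal: tie broken to the smaller of the two minimizers
  post <- list(base = gm(c(0.5, 0.5), c(-0.1, 0.1), c(0.03, 0.03)), log_norm = 0)
  class(post) <- "posterior_gm"
  t_sym <- optimal_target(post, loss)
  expect_lt(t_sym, 0)
  expect_equal(abs(t_sym), abs(optimal_target(
    structure(list(base = gm(c(0.5, 0.5), c(-0.1, 0.1), c(0.03, 0.03)),
                   log_norm = 0), class = "posterior_gm"), loss)))
  set.seed(21)
  for (i in 1:20) {
    post <- random_posterior()
    t_hat <- optimal_target(post, loss)
    grid <- gm_grid(post$base, step = 1e-5)
    t_grid <- grid[which.min(expected_loss(post, grid, loss))]
    expect_lt(abs(t_hat - t_grid), 1e-4)
  }
})

test_that("power density interpolates between matching and MAP", {
  post <- random_posterior(2)
  g <- post$base
  grid <- gm_grid(g)
  d1 <- power_density(post, 1, grid)
  expect_lt(max(abs(ddens(grid, d1) - dgm(grid, g))), 1e-12)
  # Gaussian posterior, kappa = 4: half the sd
  pg <- posterior_update(gm(1, 0, 0.1), 0.02, 0.1)
  d4 <- power_density(pg, 4)
  expect_equal(d4$mix$sds, pg$base$sds / 2)
  # large kappa concentrates at the global mode
  gb <- structure(list(base = gm(c(0.45, 0.55), c(-0.1, 0.1), c(0.03, 0.03)),
                       log_norm = 0), class = "posterior_gm")
  d50 <- power_density(gb, 50)
  mode <- gm_mode(gb$base)
  dx <- d50$x[2] - d50$x[1]
  hw <- 3 * 0.03 / sqrt(50)
  mass <- sum(d50$pdf[abs(d50$x - mode) <= hw]) * dx
  expect_gt(mass, 0.99)
})

test_that("Laplace approximation matches mode and curvature", {
  pg <- posterior_update(gm(1, 0.1, 0.07), 0.1, 0.07)
  la <- laplace_approx(pg)
  expect_equal(la$means, gm_mean(pg$base))
  expect_equal(la$sds, pg$base$sds, tolerance = 1e-8)
  # skewed mixture: narrower than the full posterior, curvature matches
  # central finite differences of the log pdf
  g <- gm(c(0.7, 0.3), c(-0.02, 0.09), c(0.03, 0.08))
  la2 <- laplace_approx(g)
  expect_lt(la2$sds^2, gm_var(g))
  h <- 1e-5
  m <- la2$means
  fd <- (dgm(m + h, g, log = TRUE) - 2 * dgm(m, g, log = TRUE) +
           dgm(m - h, g, log = TRUE)) / h^2
  expect_equal(-1 / la2$sds^2, fd, tolerance = 1e-6 * abs(fd))
})

test_that("sample-average density is exact for integer k and matches simulation", {
  post <- random_posterior(2)
  grid <- gm_grid(post$base)
  d1 <- sample_average_density(post, 1, grid)
  expect_lt(max(abs(ddens(grid, d1) - dgm(grid, post$base))), 1e-12)
  pg <- posterior_update(gm(1, 0, 0.09), 0.03, 0.09)
  d3g <- sample_average_density(pg, 3)
  expect_equal(d3g$mix$sds, pg$base$sds / sqrt(3))
  # bimodal, k = 3: exact multinomial expansion vs 1e6 simulated averages
  g <- gm(c(0.5, 0.5), c(-0.09, 0.09), c(0.035, 0.035))
  d3 <- sample_average_density(structure(list(base = g, log_norm = 0),
                                         class = "posterior_gm"), 3)
  set.seed(5)
  sims <- rowMeans(matrix(gm_sample(3e6, g), ncol = 3))
  expect_lt(ks_distance(sims, function(x) pgm(x, d3$mix)), 0.005)
  expect_error(sample_average_density(pg, 0.5), ">= 1")
})

test_that("success probability and optimality index behave as defined", {
  loss <- cfg$loss
  # posterior sd = window/2 and centred response: 2 Phi(1) - 1
  s0 <- loss$window / 2 * sqrt(2)
  p <- success_probability(gm(1, 0, s0), 0, s0, 0, loss)
  expect_equal(p, 2 * stats::pnorm(1) - 1, tolerance = 1e-12)
  expect_lt(success_probability(gm(1, 0, s0), 0, s0, 5, loss), 1e-12)
  # closed form equals quadrature of the posterior over the window
  set.seed(9)
  for (i in 1:10) {
    pr <- random_mixture(2)
    cue <- stats::runif(1, -0.1, 0.1); sd_c <- stats::runif(1, 0.05, 0.12)
    r <- stats::runif(1, -0.1, 0.1)
    post <- posterior_update(pr, cue, sd_c)$base
    num <- stats::integrate(function(x) dgm(x, post), r - loss$window / 2,
                            r + loss$window / 2, rel.tol = 1e-12)$value
    expect_equal(success_probability(pr, cue, sd_c, r, loss), num,
                 tolerance = 1e-8)
  }
  # the index is 1 at the maximizer and never exceeds 1
  pr <- gm(c(0.5, 0.5), c(-0.08, 0.08), c(0.04, 0.04))
  mx <- max_success_probability(pr, 0.02, 0.08, loss)
  expect_equal(optimality_index(pr, 0.02, 0.08, mx$response, loss), 1,
               tolerance = 1e-9)
  expect_lt(optimality_index(pr, 0.02, 0.08, 0.6, loss), 1e-3)
  set.seed(13)
  idx <- replicate(200, {
    pr <- random_mixture(2)
    optimality_index(pr, stats::runif(1, -0.1, 0.1), 0.08,
                     stats::runif(1, -0.3, 0.3), loss)
  })
  expect_true(all(idx <= 1 + 1e-9) && all(idx >= 0))
})

test_that("KL non-Gaussianity is zero for Gaussians and invariant to affine maps", {
  pg <- posterior_update(gm(1, 0, 0.1), 0.05, 0.1)
  expect_equal(as.numeric(kl_nongaussianity(pg)), 0)
  g <- gm(c(0.5, 0.5), c(-0.1, 0.1), c(0.03, 0.03))
  kl <- kl_nongaussianity(structure(list(base = g, log_norm = 0),
                                    class = "posterior_gm"))
  expect_gt(as.numeric(kl), 0.02)
  expect_true(attr(kl, "non_gaussian"))
  g2 <- gm_affine(g, shift = 0.3, scale = 2.5)
  expect_lt(abs(as.numeric(kl) -
                  as.numeric(kl_nongaussianity(structure(list(base = g2, log_norm = 0),
                                                         class = "posterior_gm")))),
            1e-9)
})

test_that("all location outputs are translation-equivariant", {
  set.seed(31)
  loss <- cfg$loss
  for (i in 1:5) {
    pr <- random_mixture(2)
    cue <- stats::runif(1, -0.1, 0.1); sd_c <- 0.07; shift <- stats::runif(1, -2, 2)
    pr2 <- gm_affine(pr, shift = shift)
    p1 <- posterior_update(pr, cue, sd_c); p2 <- posterior_update(pr2, cue + shift, sd_c)
    expect_lt(abs(gm_mean(p2$base) - gm_mean(p1$base) - shift), 1e-9)
    expect_lt(abs(optimal_target(p2, loss) - optimal_target(p1, loss) - shift), 1e-9)
    expect_lt(abs(gm_mode(p2$base) - gm_mode(p1$base) - shift), 1e-9)
    expect_lt(abs(success_probability(pr2, cue + shift, sd_c, 0.02 + shift, loss) -
                    success_probability(pr, cue, sd_c, 0.02, loss)), 1e-9)
  }
})
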