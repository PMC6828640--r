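# Frozen expected values below were computed with independent oracles:
# large-sample Monte Carlo integration over the random effects and adaptive
# quadrature (stats::integrate), not with the package's own formulas.

test_that("closed-form losses ICC matches Monte Carlo integration", {
  expect_equal(icc_losses_closed(0.5, 1.5), 0.37115, tolerance = 1e-4)
  expect_equal(icc_losses_closed(1.0, 2.0), 0.55835, tolerance = 1e-4)
  expect_equal(icc_losses_closed(0, 3), 0)
  expect_error(icc_losses_closed(-0.1, 1), "non-negative")
  expect_error(icc_losses_closed(0.5, 0), "positive")
})

test_that("losses ICC inversion is consistent and respects the supremum", {
  for (target in c(0.2, 0.45, 0.65)) {
    s2 <- icc_losses_invert(target, shape = 3)
    expect_equal(icc_losses_closed(s2, 3), target, tolerance = 1e-10)
  }
  # supremum 1/(1 + 1/alpha): alpha = 1 cannot reach 0.6
  expect_error(icc_losses_invert(0.6, shape = 1), "unattainable")
  s2 <- icc_losses_invert(0.3, shape = 0.8, family = "lognormal")
  expect_equal(icc_losses_closed(s2, 0.8, family = "lognormal"), 0.3,
               tolerance = 1e-10)
})

test_that("zero-part decomposition matches its oracle and conserves variance", {
  z <- icc_zero(0, 1)
  expect_equal(z$icc, 0.17352, tolerance = 5e-4)
  expect_equal(z$v_between + z$v_within, 0.25, tolerance = 1e-10)
  expect_equal(icc_zero(1.3, 0)$icc, 0)
  # total variance equals marginal Bernoulli variance for asymmetric eta too
  z2 <- icc_zero(1.5, 2)
  ep <- integrate(function(u) plogis(1.5 + u) * dnorm(u, 0, sqrt(2)),
                  -Inf, Inf, rel.tol = 1e-12)$value
  expect_equal(z2$v_between + z2$v_within, ep * (1 - ep), tolerance = 1e-8)
  # strictly increasing in the intercept variance
  grid <- vapply(c(0.2, 0.5, 1, 2, 4), function(s) icc_zero(0.7, s)$icc, 0)
  expect_true(all(diff(grid) > 0))
  expect_error(icc_zero(0, -1), "non-negative")
})

test_that("overall decomposition reproduces the analytic factorization", {
  p <- two_part_params("gamma", "g", beta_z0 = qlogis(0.9), beta_c0 = 0,
                       sigma_z = 0, sigma_c = sqrt(0.5), alpha = 1.5)
  o <- icc_overall(p, "g")
  expect_equal(o$v_between, 0.81 * exp(0.5) * (exp(0.5) - 1), tolerance = 1e-6)
  expect_equal(o$v_within, exp(1) * (0.9 * (1 + 1 / 1.5) - 0.81), tolerance = 1e-6)
  expect_equal(o$icc, 0.3160, tolerance = 1e-3)
})

test_that("overall ICC reduces to the losses ICC when zeros are impossible", {
  p <- two_part_params("gamma", "g", beta_z0 = 35, beta_c0 = log(800),
                       sigma_z = 0.7, sigma_c = 0.9, alpha = 2.5)
  expect_equal(icc_overall(p, "g")$icc,
               icc_losses_closed(0.81, 2.5), tolerance = 1e-8)
})

test_that("2-D quadrature agrees with the factorized rho = 0 path", {
  p <- two_part_params("gamma", "g", beta_z0 = 1.2, beta_c0 = log(600),
                       delta_z = -0.5, delta_c = 0.1,
                       sigma_z = 1.1, sigma_c = 0.8, rho = 0, alpha = 1.8)
  a <- icc_overall(p, "g", force_2d = FALSE)
  b <- icc_overall(p, "g", force_2d = TRUE, n_nodes = 48)
  expect_equal(a$icc, b$icc, tolerance = 1e-8)
})

test_that("ICCs are invariant to rescaling the outcome", {
  base <- two_part_params("gamma", "g", beta_z0 = 1.5, beta_c0 = log(400),
                          delta_c = 0.2, sigma_z = 0.9, sigma_c = 0.7,
                          rho = 0.4, alpha = 2)
  scaled <- base
  scaled$beta_c0 <- base$beta_c0 + log(100) # multiply every amount by 100
  for (comp in c("losses", "overall")) {
    expect_equal(icc_overall(base, "g", comp)$icc,
                 icc_overall(scaled, "g", comp)$icc, tolerance = 1e-10)
  }
})

test_that("quadrature matches brute-force Monte Carlo across random points", {
  set.seed(99)
  for (i in 1:5) {
    p <- two_part_params("gamma", "g",
                         beta_z0 = runif(1, -1, 3), beta_c0 = runif(1, 4, 7),
                         delta_z = runif(1, -1, 0.5), delta_c = runif(1, -.3, .3),
                         sigma_z = runif(1, 0.2, 2), sigma_c = runif(1, 0.2, 1.3),
                         rho = runif(1, -0.8, 0.8), alpha = runif(1, 0.7, 4))
    comp <- c("zero", "losses", "overall")[1 + i %% 3]
    oracle <- mc_icc_batched(p, "g", comp, n = 2e5, seed = i)
    got <- icc_overall(p, "g", comp)$icc
    expect_lt(abs(got - oracle$icc), 3 * oracle$se + 2e-3)
  }
})

test_that("between plus within equals the simulated unconditional variance", {
  p <- two_part_params("gamma", "g", beta_z0 = 1.6, beta_c0 = log(300),
                       sigma_z = 0.8, sigma_c = 0.6, rho = 0.5, alpha = 2)
  o <- icc_overall(p, "g", "overall", role_handling = "consistency")
  set.seed(31)
  n <- 4e5
  x1 <- rnorm(n); x2 <- rnorm(n)
  uz <- 0.8 * x1; uc <- 0.6 * (0.5 * x1 + sqrt(0.75) * x2)
  z <- rbinom(n, 1, plogis(1.6 + uz))
  y <- ifelse(z == 1, rgamma(n, 2, 2 / exp(log(300) + uc)), 0)
  v <- var(y)
  se_v <- sd((y - mean(y))^2) / sqrt(n)
  expect_lt(abs((o$v_between + o$v_within) - v), 3 * se_v)
})

test_that("posterior summaries of degenerate draws have zero-width intervals", {
  p <- two_part_params("gamma", "g", beta_z0 = 2, beta_c0 = log(500),
                       sigma_z = 0.7, sigma_c = 0.8, alpha = 2)
  dr <- constant_draws(p, S = 7)
  s <- posterior_icc(dr, "losses", "g")
  expect_equal(s$ci_low, s$point)
  expect_equal(s$ci_high, s$point)
  expect_equal(s$point, icc_overall(p, "g", "losses")$icc, tolerance = 1e-10)
})

test_that("group differences negate exactly under label swap", {
  p <- two_part_params("gamma", c("a", "b"), beta_z0 = c(2, 1.5),
                       beta_c0 = log(c(500, 400)), sigma_z = c(0.6, 0.9),
                       sigma_c = c(0.9, 0.6), alpha = c(2, 3))
  dr <- constant_draws(p, S = 4)
  ab <- icc_difference(dr, "losses", "a", "b")
  ba <- icc_difference(dr, "losses", "b", "a")
  expect_equal(ab$draws, -ba$draws)
  # identical parameters give a zero difference with zero width
  p2 <- two_part_params("gamma", c("a", "b"), beta_z0 = 2, beta_c0 = 6,
                        sigma_z = 0.5, sigma_c = 0.7, alpha = 2)
  d0 <- icc_difference(constant_draws(p2, 3), "overall", "a", "b")
  expect_equal(d0$point, 0, tolerance = 1e-12)
  expect_equal(d0$ci_high - d0$ci_low, 0, tolerance = 1e-12)
  expect_error(icc_difference(dr, "losses", "a", "zz"), "absent")
})

test_that("gaussian fits route through the closed-form ICC", {
  p <- two_part_params("gaussian", "g", mu = 10, sigma_b = sqrt(3), sigma_e = 1)
  dr <- constant_draws(p, S = 3)
  s <- posterior_gaussian_icc(dr, "g")
  expect_equal(s$point, 0.75)
  expect_error(posterior_icc(dr, "zero", "g"), "gaussian_icc")
})

test_that("role marginals reproduce closed-form expectations", {
  # constant hurdle p = 0.9, gamma mean 1000, sigma_c^2 = 0.5:
  # marginal mean = 0.9 * 1000 * exp(0.25)
  p <- two_part_params("gamma", "g", beta_z0 = qlogis(0.9),
                       beta_c0 = log(1000), delta_z = 0, delta_c = 0,
                       sigma_z = 0, sigma_c = sqrt(0.5), alpha = 2)
  tab <- role_marginals(constant_draws(p, 3))
  mm <- tab$point[tab$quantity == "marginal_mean_gambler"]
  expect_equal(mm, 0.9 * 1000 * exp(0.25), tolerance = 1e-4)
  # no role effect: difference 0, ratio 1, zero-width intervals
  dif <- tab[tab$quantity == "mean_diff_cso_minus_gambler", ]
  expect_equal(dif$point, 0, tolerance = 1e-8)
  expect_equal(dif$ci_high - dif$ci_low, 0, tolerance = 1e-10)
  expect_equal(tab$point[tab$quantity == "mean_ratio_cso_over_gambler"], 1,
               tolerance = 1e-10)
  # zero proportion at eta_z = 2.2 without heterogeneity
  p2 <- two_part_params("gamma", "g", beta_z0 = 2.2, beta_c0 = log(100),
                        sigma_z = 0, sigma_c = 0.3, alpha = 2)
  tab2 <- role_marginals(constant_draws(p2, 3))
  expect_equal(tab2$point[tab2$quantity == "zero_prop_gambler"],
               1 - plogis(2.2), tolerance = 1e-6)
})

test_that("correlated marginal means match Monte Carlo", {
  p <- two_part_params("gamma", "g", beta_z0 = 1, beta_c0 = log(500),
                       delta_z = -0.6, delta_c = 0.1,
                       sigma_z = 1.2, sigma_c = 0.9, rho = 0.6, alpha = 2)
  tab <- role_marginals(constant_draws(p, 3))
  set.seed(55)
  n <- 5e5
  x1 <- rnorm(n); x2 <- rnorm(n)
  uz <- 1.2 * x1; uc <- 0.9 * (0.6 * x1 + 0.8 * x2)
  mm_mc <- mean(plogis(1 + uz) * exp(log(500) + uc))
  se <- sd(plogis(1 + uz) * exp(log(500) + uc)) / sqrt(n)
  got <- tab$point[tab$quantity == "marginal_mean_gambler"]
  expect_lt(abs(got - mm_mc), 3 * se)
})
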