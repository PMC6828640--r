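test_that("refitting with the same seed reproduces the draws exactly", {
  d <- small_data()
  cfg <- quick_config()
  f1 <- suppressWarnings(fit_two_part(d, cfg))
  f2 <- suppressWarnings(fit_two_part(d, cfg))
  expect_identical(f1$draws, f2$draws)
  cfg2 <- cfg; cfg2$seed <- 8L
  f3 <- suppressWarnings(fit_two_part(d, cfg2))
  expect_false(identical(f1$draws, f3$draws))
})

test_that("draws satisfy the parameter invariants and carry diagnostics", {
  fit <- small_fit()
  expect_true(all(fit$draws$sigma_z.partner >= 0))
  expect_true(all(fit$draws$sigma_c.partner >= 0))
  expect_true(all(fit$draws$alpha.partner > 0))
  expect_true(all(abs(fit$draws$rho.partner) <= 1))
  expect_setequal(
    fit$diagnostics$param,
    c("alpha.partner", "beta_c0.partner", "beta_z0.partner", "delta_c",
      "delta_z", "sigma_c.partner", "sigma_z.partner"))
  expect_true(all(is.finite(fit$diagnostics$ess)))
  expect_equal(nrow(fit$draws), 600) # 2 chains x 300 retained iterations
})

test_that("degenerate datasets are rejected", {
  d <- small_data()
  d0 <- d; d0$y <- 0
  expect_error(fit_two_part(dyad_data(as.data.frame(d0)), quick_config()),
               "unidentifiable")
  dc <- d; dc$y <- 5
  expect_error(fit_gaussian(dyad_data(as.data.frame(dc)),
                            quick_config("gaussian")),
               "degenerate")
})

test_that("posterior medians recover the generating parameters", {
  # moderate-sized single-group scenario; medians within 3 posterior SDs
  p <- two_part_params("gamma", "partner", beta_z0 = 2, beta_c0 = 7,
                       delta_z = -0.5, delta_c = 0.1,
                       sigma_z = 1, sigma_c = 0.9, alpha = 2)
  d <- draw_dyads(sim_scenario(p, c(partner = 200), seed = 21))
  fit <- suppressWarnings(fit_two_part(
    d, fit_config("gamma", chains = 2, adapt = 300, warmup = 300, iter = 600,
                  seed = 3)))
  for (par in c("beta_c0.partner", "sigma_c.partner", "alpha.partner")) {
    truth <- c(beta_c0.partner = 7, sigma_c.partner = 0.9, alpha.partner = 2)[[par]]
    v <- fit$draws[[par]]
    expect_lt(abs(median(v) - truth), 3 * sd(v))
  }
})

test_that("modelling an absent correlation does not distort the losses part", {
  # data generated with rho = 0: the independent and correlated variants
  # should agree on the losses-part hyperparameters
  d <- draw_dyads(small_scenario(seed = 16, n = 150))
  base <- fit_config("gamma", chains = 2, adapt = 250, warmup = 250,
                     iter = 500, seed = 6)
  corr <- base; corr$correlated <- TRUE
  f_ind <- suppressWarnings(fit_two_part(d, base))
  f_cor <- suppressWarnings(fit_two_part(d, corr))
  expect_lt(abs(median(f_ind$draws$sigma_c.partner) -
                  median(f_cor$draws$sigma_c.partner)), 0.05)
  expect_lt(abs(median(f_ind$draws$alpha.partner) -
                  median(f_cor$draws$alpha.partner)), 0.05)
})

test_that("an all-positive dataset degenerates to the pure gamma GLMM", {
  p <- two_part_params("gamma", "partner", beta_z0 = 30, beta_c0 = 6.5,
                       sigma_z = 0, sigma_c = 0.8, alpha = 2)
  d <- draw_dyads(sim_scenario(p, c(partner = 80), seed = 13))
  expect_true(all(d$y > 0))
  fit <- suppressWarnings(fit_two_part(d, quick_config()))
  # hurdle intercept pushed to large positive values: p(nonzero) near 1
  expect_gt(median(plogis(fit$draws$beta_z0.partner)), 0.97)
})

test_that("the Gaussian fit recovers the classical ICC", {
  p <- two_part_params("gaussian", "pooled", mu = 100,
                       sigma_b = sqrt(3), sigma_e = 1)
  d <- draw_dyads(sim_scenario(p, c(pooled = 500), seed = 9))
  fit <- suppressWarnings(fit_gaussian(
    d, fit_config("gaussian", group_specific = FALSE, chains = 2,
                  adapt = 300, warmup = 300, iter = 600, seed = 2)))
  s <- posterior_gaussian_icc(fit, "pooled")
  expect_lt(abs(s$point - 0.75), 0.05)
})

test_that("lognormal positive parts are supported", {
  p <- two_part_params("lognormal", "partner", beta_z0 = 2.5, beta_c0 = 6,
                       sigma_z = 0.5, sigma_c = 0.8, s2 = 0.6)
  d <- draw_dyads(sim_scenario(p, c(partner = 80), seed = 14))
  fit <- suppressWarnings(fit_two_part(d, quick_config("lognormal")))
  expect_true("s2.partner" %in% names(fit$draws))
  expect_lt(abs(median(fit$draws$s2.partner) - 0.6), 0.4)
})

test_that("convergence checking flags bad chains and handles edge cases", {
  fit <- small_fit()
  rep <- check_convergence(fit)
  expect_s3_class(rep$table, "data.frame")
  expect_true(is.logical(rep$pass) || is.na(rep$pass))

  # chains started from deliberately different distributions, no mixing:
  # construct a draws object whose two chains sit at different levels
  bad <- fit
  S <- nrow(bad$draws)
  half <- seq_len(S / 2)
  bad$draws$beta_c0.partner[half] <- bad$draws$beta_c0.partner[half] + 50
  chains <- split(seq_len(S), bad$chain)
  mcl <- coda::as.mcmc.list(lapply(chains, function(ix) {
    coda::mcmc(as.matrix(bad$draws[ix, "beta_c0.partner", drop = FALSE]))
  }))
  rhat <- coda::gelman.diag(mcl, multivariate = FALSE, autoburnin = FALSE)$psrf[1, 1]
  bad$diagnostics$rhat[bad$diagnostics$param == "beta_c0.partner"] <- rhat
  expect_gt(rhat, 1.05)
  expect_false(check_convergence(bad)$pass)

  # single chain: limited diagnostics, explicitly noted
  one <- fit
  one$sampler$chains <- 1L
  one$diagnostics$rhat <- NA_real_
  rep1 <- check_convergence(one)
  expect_true(is.na(rep1$pass))
  expect_match(rep1$note, "chains")

  empty <- fit; empty$draws <- fit$draws[0, ]
  expect_error(check_convergence(empty), "no posterior draws")
})
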