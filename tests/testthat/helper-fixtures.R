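# Shared fixtures: small scenarios, degenerate posterior-draw objects, and
# memoized fits so that expensive MCMC runs are shared across tests.

fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(fixture_cache[[key]])) fixture_cache[[key]] <- force(expr)
  fixture_cache[[key]]
}

small_scenario <- function(seed = 1, n = 40, rho = 0) {
  p <- two_part_params("gamma", "partner",
                       beta_z0 = 2.2, beta_c0 = log(1000),
                       delta_z = -0.5, delta_c = 0.1,
                       sigma_z = 0.8, sigma_c = 0.9, rho = rho, alpha = 2)
  sim_scenario(p, c(partner = n), seed = seed)
}

quick_config <- function(family = "gamma", ...) {
  fit_config(family, chains = 2, adapt = 150, warmup = 150, iter = 300,
             seed = 7, ...)
}

small_fit <- function() {
  cached("small_fit", {
    d <- draw_dyads(small_scenario(seed = 4, n = 60))
    suppressWarnings(fit_two_part(d, quick_config()))
  })
}

small_data <- function() {
  cached("small_data", draw_dyads(small_scenario(seed = 4, n = 60)))
}

# Degenerate draws object: the same parameter point replicated S times, in
# the layout produced by fit_two_part. Used to test posterior summaries
# against closed-form single-point values.
constant_draws <- function(params, S = 5, n_dyads = NULL) {
  stopifnot(inherits(params, "two_part_params"))
  cols <- list()
  stubs <- if (params$family == "gaussian") {
    c("mu", "sigma_b", "sigma_e")
  } else {
    c("beta_z0", "beta_c0", "sigma_z", "sigma_c", "rho",
      if (params$family == "gamma") "alpha" else "s2")
  }
  for (g in params$groups) {
    for (s in stubs) cols[[paste0(s, ".", g)]] <- rep(params[[s]][[g]], S)
  }
  if (params$family == "gaussian") {
    cols[["delta"]] <- rep(params$delta, S)
  } else {
    cols[["delta_z"]] <- rep(params$delta_z, S)
    cols[["delta_c"]] <- rep(params$delta_c, S)
  }
  if (is.null(n_dyads)) {
    n_dyads <- stats::setNames(rep(50L, length(params$groups)), params$groups)
  }
  structure(list(
    draws = as.data.frame(cols), chain = rep(1L, S),
    family = params$family, groups = params$groups,
    group_specific = TRUE, correlated = TRUE, include_role = TRUE,
    n_dyads_per_group = n_dyads,
    diagnostics = data.frame(param = names(cols), rhat = 1, ess = S),
    converged = TRUE,
    sampler = list(chains = 1L, adapt = 0L, warmup = 0L, iter = S, seed = 1L)),
    class = "dyadicc_draws")
}

# Monte Carlo decomposition of the data-scale variance for one group:
# independent oracle for the quadrature/closed-form path, implementing the
# same absolute-agreement convention by brute force.
mc_decompose <- function(params, group, component, n = 1e6, seed = 1,
                         role_handling = "absolute") {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  g <- group
  sz <- params$sigma_z[[g]]; sc <- params$sigma_c[[g]]; r <- params$rho[[g]]
  x1 <- rnorm(n); x2 <- rnorm(n)
  uz <- sz * x1
  uc <- sc * (r * x1 + sqrt(1 - r^2) * x2)
  shape <- if (params$family == "gamma") params$alpha[[g]] else params$s2[[g]]
  kappa <- if (params$family == "gamma") 1 / shape else exp(shape) - 1
  mean_corr <- if (params$family == "gamma") 0 else shape / 2
  p0 <- plogis(params$beta_z0[[g]] + uz)
  p1 <- plogis(params$beta_z0[[g]] + params$delta_z + uz)
  m0 <- exp(params$beta_c0[[g]] + mean_corr + uc)
  m1 <- exp(params$beta_c0[[g]] + params$delta_c + mean_corr + uc)
  if (component == "zero") {
    pb <- (p0 + p1) / 2
    v_b <- var(pb)
    v_w <- mean((p0 * (1 - p0) + p1 * (1 - p1)) / 2)
    if (role_handling == "absolute") v_w <- v_w + mean((p0 - p1)^2 / 4)
  } else if (component == "losses") {
    mb <- (m0 + m1) / 2
    v_b <- var(mb)
    v_w <- mean((m0^2 + m1^2) / 2 * kappa)
    if (role_handling == "absolute") v_w <- v_w + mean((m0 - m1)^2 / 4)
  } else {
    mu0 <- p0 * m0; mu1 <- p1 * m1
    mb <- (mu0 + mu1) / 2
    v_b <- var(mb)
    cv0 <- (1 + kappa) * p0 * m0^2 - mu0^2
    cv1 <- (1 + kappa) * p1 * m1^2 - mu1^2
    v_w <- mean((cv0 + cv1) / 2)
    if (role_handling == "absolute") v_w <- v_w + mean((mu0 - mu1)^2 / 4)
  }
  list(v_between = v_b, v_within = v_w, icc = v_b / (v_b + v_w))
}

# batched Monte Carlo ICC with a standard error, for 3-SE comparisons
mc_icc_batched <- function(params, group, component, n = 1e6, seed = 1,
                           batches = 10, role_handling = "absolute") {
  iccs <- vapply(seq_len(batches), function(b) {
    mc_decompose(params, group, component, n = n / batches,
                 seed = seed * 1000 + b, role_handling = role_handling)$icc
  }, 0)
  list(icc = mean(iccs), se = sd(iccs) / sqrt(batches))
}
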