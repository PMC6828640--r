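#' Fit configuration
#'
#' Sampler and model settings for [fit_two_part()] and [fit_gaussian()].
#' Priors are weakly informative by default: half-Student-t(3, scale 2.5)
#' on all random-effect and residual SDs, Student-t(3, 0, 5) on
#' intercepts, normal(0, 2.5) on the rater-role effects, uniform(-1, 1)
#' on the random-intercept correlation, and normal(0, sd 2) on the log of
#' the gamma shape.
#'
#' @param family `"gamma"`, `"lognormal"` or `"gaussian"`.
#' @param correlated model the correlation between the two random
#'   intercepts (two-part families only); `FALSE` fixes `rho = 0`.
#' @param group_specific free the random-effect SDs, dispersion and
#'   intercepts per relationship group; `FALSE` pools all groups.
#' @param include_role include the CSO-vs-gambler fixed effects
#'   `delta_z`, `delta_c` (shared across groups).
#' @param chains,adapt,warmup,iter MCMC layout: number of chains, JAGS
#'   adaptation steps, burn-in iterations discarded after adaptation, and
#'   retained sampling iterations per chain.
#' @param seed integer; fixes the per-chain RNG so that refits are
#'   reproducible draw for draw.
#' @param priors named list overriding `intercept_scale`, `sd_scale`,
#'   `role_scale`, `logshape_sd`.
#' @return object of class `fit_config`.
#' @export
fit_config <- function(family = c("gamma", "lognormal", "gaussian"),
                       correlated = FALSE, group_specific = TRUE,
                       include_role = TRUE,
                       chains = 2L, adapt = 500L, warmup = 500L, iter = 1000L,
                       seed = 1L, priors = list()) {
  family <- match.arg(family)
  stopifnot(chains >= 1, iter >= 1, warmup >= 0, adapt >= 0)
  pr <- utils::modifyList(list(intercept_scale = 5, sd_scale = 2.5,
                               role_scale = 2.5, logshape_sd = 2), priors)
  structure(list(family = family, correlated = correlated,
                 group_specific = group_specific, include_role = include_role,
                 chains = as.integer(chains), adapt = as.integer(adapt),
                 warmup = as.integer(warmup), iter = as.integer(iter),
                 seed = as.integer(seed), priors = pr),
            class = "fit_config")
}

two_part_model_string <- function(config) {
  pr <- config$priors
  prec_b <- 1 / pr$intercept_scale^2
  prec_s <- 1 / pr$sd_scale^2
  prec_r <- 1 / pr$role_scale^2
  prec_la <- 1 / pr$logshape_sd^2
  pos_lik <- if (config$family == "gamma") "
    ypos[j] ~ dgamma(alpha[gp[j]], rt[j])
    rt[j] <- alpha[gp[j]] / mus[j]
    log(mus[j]) <- beta_c0[gp[j]] + delta_c * rolep[j] + u_c[dyadp[j]]" else "
    ypos[j] ~ dlnorm(lmu[j], tau_c[gp[j]])
    lmu[j] <- beta_c0[gp[j]] + delta_c * rolep[j] + u_c[dyadp[j]]"
  disp <- if (config$family == "gamma") sprintf("
    la[k] ~ dnorm(0, %g)
    alpha[k] <- exp(la[k])", prec_la) else sprintf("
    sd_log[k] ~ dt(0, %g, 3) T(0,)
    tau_c[k] <- 1 / (sd_log[k] * sd_log[k])
    s2[k] <- sd_log[k] * sd_log[k]", prec_s)
  rho <- if (config$correlated) "rho[k] ~ dunif(-1, 1)" else "rho[k] <- 0"
  role <- if (config$include_role) sprintf(
    "delta_z ~ dnorm(0, %g)\n  delta_c ~ dnorm(0, %g)", prec_r, prec_r
  ) else "delta_z <- 0\n  delta_c <- 0"
  sprintf("
model {
  for (d in 1:D) {
    raw1[d] ~ dnorm(0, 1)
    raw2[d] ~ dnorm(0, 1)
    u_z[d] <- sigma_z[gd[d]] * raw1[d]
    u_c[d] <- sigma_c[gd[d]] * (rho[gd[d]] * raw1[d] +
                                sqrt(1 - rho[gd[d]]^2) * raw2[d])
  }
  for (i in 1:N) {
    z[i] ~ dbern(p[i])
    logit(p[i]) <- beta_z0[g[i]] + delta_z * role[i] + u_z[dyad[i]]
  }
  for (j in 1:Npos) {%s
  }
  for (k in 1:G) {
    beta_z0[k] ~ dt(0, %g, 3)
    beta_c0[k] ~ dt(0, %g, 3)
    sigma_z[k] ~ dt(0, %g, 3) T(0,)
    sigma_c[k] ~ dt(0, %g, 3) T(0,)
    %s%s
  }
  %s
}", pos_lik, prec_b, prec_b, prec_s, prec_s, rho, disp, role)
}

# Priors scale with the outcome SD (passed as data `sdy`) so the model is
# usable on raw currency units without rescaling.
gaussian_model_string <- function(config) {
  pr <- config$priors
  role <- if (config$include_role) "delta ~ dnorm(0, prec_s)" else "delta <- 0"
  sprintf("
model {
  prec_s <- 1 / (%g * sdy * %g * sdy)
  for (d in 1:D) {
    b[d] ~ dnorm(0, tau_b[gd[d]])
  }
  for (i in 1:N) {
    y[i] ~ dnorm(mu[g[i]] + delta * role[i] + b[dyad[i]], tau_e[g[i]])
  }
  for (k in 1:G) {
    mu[k] ~ dnorm(ybar, 1 / (100 * sdy * sdy))
    sigma_b[k] ~ dt(0, prec_s, 3) T(0,)
    sigma_e[k] ~ dt(0, prec_s, 3) T(0,)
    tau_b[k] <- 1 / (sigma_b[k] * sigma_b[k])
    tau_e[k] <- 1 / (sigma_e[k] * sigma_e[k])
  }
  %s
}", pr$sd_scale, pr$sd_scale, role)
}

# shared indexing of a dyad_data for JAGS
jags_index <- function(data, group_specific) {
  glev <- if (group_specific) sort(unique(data$group)) else "pooled"
  gidx <- if (group_specific) match(data$group, glev) else rep(1L, nrow(data))
  dlev <- unique(data$dyad_id)
  didx <- match(data$dyad_id, dlev)
  gd <- integer(length(dlev))
  gd[didx] <- gidx
  list(glev = glev, g = gidx, dyad = didx, gd = gd, D = length(dlev))
}

#' Fit the Bayesian two-part mixed model
#'
#' Posterior sampling (MCMC via JAGS) for the dyadic two-part hurdle
#' GLMM: a logistic mixed model for the zero indicator and a gamma or
#' lognormal mixed model for the positive amounts, with dyad-level random
#' intercepts in both parts (non-centered parameterization), optionally
#' correlated. The observation-level likelihood is exactly
#' [log_density()]. Convergence is summarized per scalar parameter by the
#' potential scale reduction factor (Rhat) and the effective sample size;
#' any Rhat above 1.05 triggers a warning and sets `converged = FALSE`.
#'
#' @param data a [dyad_data] object.
#' @param config a [fit_config] with family `"gamma"` or `"lognormal"`.
#' @return object of class `dyadicc_draws`: `$draws` is a data frame with
#'   one row per retained draw (chains stacked, `$chain` gives the chain
#'   index) and one column per scalar parameter (per-group parameters are
#'   suffixed `.group`), `$diagnostics` the Rhat/ESS table, plus sampler
#'   metadata.
#' @export
fit_two_part <- function(data, config = fit_config()) {
  stopifnot(inherits(data, "dyad_data"))
  if (!config$family %in% c("gamma", "lognormal")) {
    stop("fit_two_part requires family 'gamma' or 'lognormal'")
  }
  if (all(data$y == 0)) {
    stop("all outcomes are zero: the positive part is unidentifiable")
  }
  idx <- jags_index(data, config$group_specific)
  pos <- data$y > 0
  jd <- list(D = idx$D, N = nrow(data), z = as.integer(pos), g = idx$g,
             role = as.numeric(data$role == "cso"), dyad = idx$dyad,
             gd = idx$gd, G = length(idx$glev),
             Npos = sum(pos), ypos = data$y[pos], gp = idx$g[pos],
             rolep = as.numeric(data$role == "cso")[pos],
             dyadp = idx$dyad[pos])
  monitors <- c("beta_z0", "beta_c0", "sigma_z", "sigma_c",
                if (config$family == "gamma") "alpha" else "s2",
                if (config$correlated) "rho",
                if (config$include_role) c("delta_z", "delta_c"))
  samples <- run_jags(two_part_model_string(config), jd, monitors, config)
  finish_draws(samples, config, idx$glev, data,
               fixed = c(if (!config$correlated) "rho",
                         if (!config$include_role) c("delta_z", "delta_c")))
}

#' Fit the Gaussian comparison model
#'
#' Classical two-level random-intercept linear mixed model on the raw
#' outcome (zeros included), sampled with the same MCMC backend and
#' summarized the same way as the two-part model.
#'
#' @inheritParams fit_two_part
#' @param config a [fit_config] with `family = "gaussian"`.
#' @return a `dyadicc_draws` object with per-group parameters `mu`,
#'   `sigma_b`, `sigma_e` and (optionally) the role effect `delta`.
#' @export
fit_gaussian <- function(data, config = fit_config(family = "gaussian")) {
  stopifnot(inherits(data, "dyad_data"))
  if (stats::sd(data$y) == 0) {
    stop("constant outcome: the Gaussian model is degenerate")
  }
  idx <- jags_index(data, config$group_specific)
  jd <- list(D = idx$D, N = nrow(data), y = data$y, g = idx$g,
             role = as.numeric(data$role == "cso"), dyad = idx$dyad,
             gd = idx$gd, G = length(idx$glev), ybar = mean(data$y),
             sdy = stats::sd(data$y))
  monitors <- c("mu", "sigma_b", "sigma_e",
                if (config$include_role) "delta")
  config$family <- "gaussian"
  samples <- run_jags(gaussian_model_string(config), jd, monitors, config)
  finish_draws(samples, config, idx$glev, data,
               fixed = if (!config$include_role) "delta")
}

run_jags <- function(model_string, jags_data, monitors, config) {
  inits <- lapply(seq_len(config$chains), function(ch) {
    list(.RNG.name = "base::Mersenne-Twister",
         .RNG.seed = as.integer((abs(as.numeric(config$seed)) * 1009 + ch * 7) %%
                                  2147483629))
  })
  model <- rjags::jags.model(textConnection(model_string), data = jags_data,
                             inits = inits, n.chains = config$chains,
                             n.adapt = config$adapt, quiet = TRUE)
  if (config$warmup > 0) stats::update(model, config$warmup, progress.bar = "none")
  rjags::coda.samples(model, monitors, n.iter = config$iter,
                      progress.bar = "none")
}

finish_draws <- function(samples, config, glev, data, fixed = character()) {
  mat <- do.call(rbind, lapply(samples, as.matrix))
  chain <- rep(seq_along(samples), each = config$iter)
  cols <- colnames(mat)
  # rename "beta_z0[2]" -> "beta_z0.<group>"; scalars keep their name
  per_group <- c("beta_z0", "beta_c0", "sigma_z", "sigma_c", "alpha", "s2",
                 "rho", "mu", "sigma_b", "sigma_e")
  renamed <- vapply(cols, function(nm) {
    m <- regmatches(nm, regexec("^([A-Za-z_0-9]+)\\[([0-9]+)\\]$", nm))[[1]]
    if (length(m)) return(paste0(m[2], ".", glev[as.integer(m[3])]))
    # JAGS drops the index for length-1 vectors
    if (nm %in% per_group) paste0(nm, ".", glev[1]) else nm
  }, "")
  draws <- as.data.frame(mat)
  names(draws) <- unname(renamed)
  diag <- diagnostics_table(samples)
  diag$param <- unname(renamed[match(diag$param, cols)])
  converged <- !any(diag$rhat > 1.05, na.rm = TRUE)
  out <- structure(list(
    draws = draws, chain = chain, family = config$family,
    groups = glev, group_specific = config$group_specific,
    correlated = isTRUE(config$correlated),
    include_role = isTRUE(config$include_role),
    n_dyads_per_group = fitted_dyad_counts(data, glev),
    diagnostics = diag, converged = converged,
    sampler = config[c("chains", "adapt", "warmup", "iter", "seed")]),
    class = "dyadicc_draws")
  # parameters fixed by the model variant appear as constants for downstream code
  for (f in fixed) {
    if (f %in% c("rho")) {
      for (g in glev) out$draws[[paste0("rho.", g)]] <- 0
    } else {
      out$draws[[f]] <- 0
    }
  }
  if (!converged) {
    warning("potential scale reduction above 1.05 for: ",
            paste(diag$param[which(diag$rhat > 1.05)], collapse = ", "),
            " - treat the fit as non-converged", call. = FALSE)
  }
  out
}

fitted_dyad_counts <- function(data, glev) {
  if (identical(glev, "pooled")) {
    return(c(pooled = length(unique(data$dyad_id))))
  }
  dyad_counts(data)[glev]
}

diagnostics_table <- function(samples) {
  cols <- colnames(samples[[1]])
  ess <- coda::effectiveSize(samples)
  if (length(samples) >= 2) {
    keep <- vapply(cols, function(cc) {
      stats::var(unlist(lapply(samples, function(s) as.numeric(s[, cc])))) > 0
    }, TRUE)
    rhat <- rep(NA_real_, length(cols))
    if (any(keep)) {
      sub <- lapply(samples, function(s) s[, cols[keep], drop = FALSE])
      gd <- coda::gelman.diag(coda::as.mcmc.list(lapply(sub, coda::mcmc)),
                              multivariate = FALSE, autoburnin = FALSE)
      rhat[keep] <- gd$psrf[, 1]
    }
  } else {
    rhat <- rep(NA_real_, length(cols))
  }
  data.frame(param = cols, rhat = rhat, ess = as.numeric(ess[cols]),
             row.names = NULL)
}

#' Convergence report
#'
#' @param draws a `dyadicc_draws` object.
#' @param threshold Rhat threshold for the pass flag.
#' @return list with the diagnostics `table`, a boolean `pass`, and a
#'   `note` (e.g. when only one chain was run and Rhat is unavailable).
#' @export
check_convergence <- function(draws, threshold = 1.05) {
  if (is.null(draws$draws) || nrow(draws$draws) == 0) {
    stop("no posterior draws to diagnose")
  }
  tab <- draws$diagnostics
  note <- ""
  if (draws$sampler$chains < 2 || all(is.na(tab$rhat))) {
    note <- "fewer than 2 chains: potential scale reduction unavailable; ESS only"
    pass <- NA
  } else {
    pass <- !any(tab$rhat > threshold, na.rm = TRUE)
  }
  list(table = tab, pass = pass, threshold = threshold, note = note)
}

#' @export
print.dyadicc_draws <- function(x, ...) {
  cat(sprintf("Posterior draws: %s model, %d draws (%d chains x %d iterations)\n",
              x$family, nrow(x$draws), x$sampler$chains, x$sampler$iter))
  cat("Groups:", paste(x$groups, collapse = ", "),
      if (x$correlated) "(correlated random effects)" else "(independent random effects)",
      "\n")
  q <- t(apply(x$draws, 2, stats::quantile, c(.025, .5, .975)))
  colnames(q) <- c("2.5%", "median", "97.5%")
  print(round(q, 3))
  cat(if (x$converged) "All Rhat <= 1.05\n" else "WARNING: convergence flagged\n")
  invisible(x)
}
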