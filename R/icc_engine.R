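#' @name icc_engine
#' @title Observed-data-scale variance decomposition and ICCs
#'
#' @description
#' The agreement measures of this package are intraclass correlations on
#' the observed data scale: the variance of the semicontinuous outcome is
#' split into a between-dyad and a within-dyad part by integrating the
#' conditional moments of the two-part model over the dyad random
#' intercepts, separately for the zero indicator ("zero" component), the
#' strictly positive amounts ("losses" component) and the full outcome
#' ("overall"). Integrals over the logistic-normal zero part use
#' Gauss-Hermite quadrature; moments of the lognormally distributed
#' conditional mean have closed forms.
NULL

# ---- Gauss-Hermite machinery -------------------------------------------

# nodes/weights such that E[f(U)] = sum(w * f(x)) for U ~ N(0,1)
gh_rule <- local({
  cache <- new.env(parent = emptyenv())
  function(n) {
    key <- as.character(n)
    if (is.null(cache[[key]])) {
      r <- pracma::gaussHermite(n)
      cache[[key]] <- list(x = sqrt(2) * r$x, w = r$w / sqrt(pi))
    }
    cache[[key]]
  }
})

# E[f(eta + sigma*U)] for U~N(0,1), vectorized over draws (rows).
# eta, sigma: length-S vectors; f applied elementwise to an S x K matrix.
gh_expect <- function(f, eta, sigma, n_nodes) {
  r <- gh_rule(n_nodes)
  z <- outer(eta, rep(1, n_nodes)) + outer(sigma, r$x)
  as.numeric(f(z) %*% r$w)
}

# ---- closed-form losses ICC --------------------------------------------

#' Closed-form data-scale ICC of the losses part
#'
#' For the strictly positive part of the two-part model the conditional
#' mean is lognormal in the dyad intercept, so the data-scale ICC has a
#' closed form that does not involve the intercept. With `A = exp(sigma_c2)`:
#' gamma family `(A - 1) / ((A - 1) + A / alpha)`; lognormal family
#' `(A - 1) / ((A - 1) + A * (exp(s2) - 1))`.
#'
#' @param sigma_c2 variance of the dyad random intercept of the positive
#'   part (log scale), `>= 0`.
#' @param shape gamma shape `alpha` (`family = "gamma"`) or lognormal
#'   log-scale variance `s2` (`family = "lognormal"`); `> 0`.
#' @param family `"gamma"` or `"lognormal"`.
#' @return ICC in `[0, 1)`.
#' @examples
#' icc_losses_closed(0.5, 1.5) # about 0.371
#' @export
icc_losses_closed <- function(sigma_c2, shape, family = c("gamma", "lognormal")) {
  family <- match.arg(family)
  if (any(sigma_c2 < 0)) stop("sigma_c2 must be non-negative")
  if (any(shape <= 0)) stop("shape must be positive")
  a <- exp(sigma_c2)
  kappa <- if (family == "gamma") 1 / shape else exp(shape) - 1
  (a - 1) / ((a - 1) + a * kappa)
}

#' Invert the losses ICC for the random-intercept variance
#'
#' Solves [icc_losses_closed] for `sigma_c2` at a target ICC and fixed
#' dispersion; used to construct simulation scenarios with known truth.
#'
#' @param icc target losses ICC in `[0, 1)`.
#' @inheritParams icc_losses_closed
#' @return `sigma_c2 >= 0`. Errors if the target exceeds the attainable
#'   supremum `1 / (1 + kappa)` for the given dispersion.
#' @export
icc_losses_invert <- function(icc, shape, family = c("gamma", "lognormal")) {
  family <- match.arg(family)
  if (any(icc < 0 | icc >= 1)) stop("icc must lie in [0, 1)")
  kappa <- if (family == "gamma") 1 / shape else exp(shape) - 1
  den <- 1 - icc - icc * kappa
  if (any(den <= 0)) {
    stop(sprintf("losses ICC %.3f unattainable: supremum is %.3f for this dispersion",
                 max(icc), 1 / (1 + kappa)))
  }
  log((1 - icc) / den)
}

# ---- zero-part decomposition -------------------------------------------

#' Data-scale variance decomposition of the zero part
#'
#' With `p(u) = plogis(eta_bar_z + u)` and `u ~ N(0, sigma_z2)`, the
#' between-dyad variance is `Var[p(u)]` and the within-dyad variance is
#' `E[p(u) (1 - p(u))]`; their sum equals the marginal Bernoulli variance.
#' Integrals use Gauss-Hermite quadrature with a node-doubling convergence
#' check and an optional Monte Carlo fallback.
#'
#' @param eta_bar_z logit-scale linear predictor at `u = 0`.
#' @param sigma_z2 variance of the dyad intercept, `>= 0`.
#' @param n_nodes number of quadrature nodes (at least 64 used).
#' @param fallback `"error"` (default) or `"mc"`: behaviour when doubling
#'   the nodes changes the ICC by more than `1e-8`.
#' @return list with `component = "zero"`, `v_between`, `v_within`, `icc`.
#' @export
icc_zero <- function(eta_bar_z, sigma_z2, n_nodes = 64,
                     fallback = c("error", "mc")) {
  fallback <- match.arg(fallback)
  if (sigma_z2 < 0) stop("sigma_z2 must be non-negative")
  n_nodes <- max(64L, as.integer(n_nodes))
  dec1 <- zero_decompose_vec(eta_bar_z, eta_bar_z, sqrt(sigma_z2),
                             role_handling = "consistency", n_nodes = n_nodes)
  dec2 <- zero_decompose_vec(eta_bar_z, eta_bar_z, sqrt(sigma_z2),
                             role_handling = "consistency", n_nodes = 2L * n_nodes)
  if (abs(icc_of(dec1) - icc_of(dec2)) > 1e-8) {
    if (fallback == "error") {
      stop("Gauss-Hermite quadrature did not converge under node doubling; ",
           "retry with fallback = \"mc\"")
    }
    u <- stats::qnorm((seq_len(1e6) - 0.5) / 1e6, sd = sqrt(sigma_z2))
    p <- stats::plogis(eta_bar_z + u)
    dec2 <- list(v_between = mean(p^2) - mean(p)^2, v_within = mean(p * (1 - p)))
  }
  list(component = "zero", v_between = dec2$v_between,
       v_within = dec2$v_within, icc = icc_of(dec2))
}

icc_of <- function(dec) dec$v_between / (dec$v_between + dec$v_within)

# Vectorized over draws. eta0/eta1: logit predictors of the two roles at
# u = 0; sigma_z: SD of the dyad intercept. Under "absolute" handling the
# systematic role difference contributes to the within-dyad variance.
zero_decompose_vec <- function(eta0, eta1, sigma_z,
                               role_handling = c("absolute", "consistency"),
                               n_nodes = 64) {
  role_handling <- match.arg(role_handling)
  r <- gh_rule(n_nodes)
  k <- length(r$x)
  u <- outer(sigma_z, r$x)
  p0 <- stats::plogis(outer(eta0, rep(1, k)) + u)
  p1 <- stats::plogis(outer(eta1, rep(1, k)) + u)
  pbar <- (p0 + p1) / 2
  e1 <- as.numeric(pbar %*% r$w)
  e2 <- as.numeric(pbar^2 %*% r$w)
  v_b <- e2 - e1^2
  v_w <- as.numeric(((p0 * (1 - p0) + p1 * (1 - p1)) / 2) %*% r$w)
  if (role_handling == "absolute") {
    v_w <- v_w + as.numeric(((p0 - p1)^2 / 4) %*% r$w)
  }
  list(v_between = v_b, v_within = v_w)
}

# ---- losses-part decomposition (closed form) ---------------------------

# c0/c1: conditional-mean multipliers exp(a_r) of the two roles (for the
# lognormal family the s2/2 mean correction is already absorbed);
# sigma_c2: intercept variance; kappa: Var(w|u)/m^2.
losses_decompose_vec <- function(c0, c1, sigma_c2, kappa,
                                 role_handling = c("absolute", "consistency")) {
  role_handling <- match.arg(role_handling)
  a <- exp(sigma_c2)
  cbar <- (c0 + c1) / 2
  v_b <- cbar^2 * a * (a - 1)
  v_w <- (c0^2 + c1^2) / 2 * a^2 * kappa
  if (role_handling == "absolute") v_w <- v_w + (c0 - c1)^2 / 4 * a^2
  list(v_between = v_b, v_within = v_w)
}

# ---- overall decomposition ---------------------------------------------

#' Data-scale variance decomposition of the overall outcome
#'
#' Decomposes the variance of the semicontinuous outcome
#' `y = z * w` (zero indicator times positive amount) for one relationship
#' group: the between-dyad variance is the variance over the random
#' intercepts of the dyad-level conditional mean, and the within-dyad
#' variance is the expectation of the conditional variance from
#' [conditional_moments]. When the two random intercepts are independent
#' (`rho = 0`) the zero and losses integrals factorize (1-D quadrature and
#' closed forms); otherwise a 2-D Gauss-Hermite rule over the correlated
#' intercepts is used. With `role_handling = "absolute"` (default) the
#' systematic CSO-vs-gambler difference counts as within-dyad
#' disagreement; `"consistency"` ignores it.
#'
#' @param params a [two_part_params] object (gamma or lognormal).
#' @param group group label.
#' @param component `"overall"`, `"losses"` or `"zero"`.
#' @param role_handling `"absolute"` or `"consistency"`.
#' @param n_nodes Gauss-Hermite nodes per axis (minimum 32 enforced for
#'   the 2-D rule).
#' @param force_2d compute via the 2-D rule even when `rho = 0` (used to
#'   verify internal consistency).
#' @return list with `component`, `v_between`, `v_within`, `icc`.
#' @export
icc_overall <- function(params, group, component = "overall",
                        role_handling = c("absolute", "consistency"),
                        n_nodes = 32, force_2d = FALSE) {
  role_handling <- match.arg(role_handling)
  validate_two_part_params(params)
  if (params$family == "gaussian") {
    stop("data-scale decomposition applies to the two-part families; ",
         "use gaussian_icc for the Gaussian model")
  }
  check_group_role(params, group, "gambler")
  v <- draws_decompose(param_row(params, group), params$family, component,
                       role_handling, n_nodes = n_nodes, force_2d = force_2d)
  list(component = component, v_between = v$v_between, v_within = v$v_within,
       icc = icc_of(v))
}

# flatten one group of a two_part_params into the per-draw row layout
param_row <- function(params, group) {
  list(beta_z0 = params$beta_z0[[group]], beta_c0 = params$beta_c0[[group]],
       delta_z = params$delta_z, delta_c = params$delta_c,
       sigma_z = params$sigma_z[[group]], sigma_c = params$sigma_c[[group]],
       rho = params$rho[[group]],
       shape = if (params$family == "gamma") params$alpha[[group]] else params$s2[[group]])
}

# Core per-draw decomposition; every element of `pr` may be a length-S
# vector. Returns v_between / v_within vectors.
draws_decompose <- function(pr, family, component, role_handling,
                            n_nodes = 32, force_2d = FALSE,
                            include_role = TRUE) {
  dz <- if (include_role) pr$delta_z else 0
  dc <- if (include_role) pr$delta_c else 0
  kappa <- if (family == "gamma") 1 / pr$shape else exp(pr$shape) - 1
  mean_corr <- if (family == "gamma") 0 else pr$shape / 2
  c0 <- exp(pr$beta_c0 + mean_corr)         # gambler conditional-mean multiplier
  c1 <- exp(pr$beta_c0 + dc + mean_corr)    # cso
  if (component == "zero") {
    return(zero_decompose_vec(pr$beta_z0, pr$beta_z0 + dz, pr$sigma_z,
                              role_handling, n_nodes = max(64, n_nodes)))
  }
  if (component == "losses") {
    return(losses_decompose_vec(c0, c1, pr$sigma_c^2, kappa, role_handling))
  }
  if (component != "overall") stop("unknown component: ", component)
  if (any(pr$rho != 0) || force_2d) {
    overall_decompose_2d(pr, c0, c1, dz, kappa, role_handling,
                         n_nodes = max(32, n_nodes))
  } else {
    overall_decompose_factorized(pr, c0, c1, dz, kappa, role_handling,
                                 n_nodes = max(64, n_nodes))
  }
}

# rho = 0: zero-part moments by 1-D quadrature, losses moments closed form
overall_decompose_factorized <- function(pr, c0, c1, dz, kappa,
                                         role_handling, n_nodes) {
  r <- gh_rule(n_nodes)
  k <- length(r$x)
  u <- outer(pr$sigma_z, r$x)
  p0 <- stats::plogis(outer(pr$beta_z0, rep(1, k)) + u)
  p1 <- stats::plogis(outer(pr$beta_z0 + dz, rep(1, k)) + u)
  ep0 <- as.numeric(p0 %*% r$w); ep1 <- as.numeric(p1 %*% r$w)
  ep00 <- as.numeric(p0^2 %*% r$w); ep11 <- as.numeric(p1^2 %*% r$w)
  ep01 <- as.numeric((p0 * p1) %*% r$w)
  s2c <- pr$sigma_c^2
  e1c <- exp(s2c / 2)   # E[exp(u_c)]
  e2c <- exp(2 * s2c)   # E[exp(2 u_c)]
  mu1 <- (ep0 * c0 + ep1 * c1) / 2 * e1c
  mu2 <- (ep00 * c0^2 + 2 * ep01 * c0 * c1 + ep11 * c1^2) / 4 * e2c
  v_b <- mu2 - mu1^2
  v_w <- ((1 + kappa) * (ep0 * c0^2 + ep1 * c1^2) -
            (ep00 * c0^2 + ep11 * c1^2)) / 2 * e2c
  if (role_handling == "absolute") {
    v_w <- v_w + (ep00 * c0^2 - 2 * ep01 * c0 * c1 + ep11 * c1^2) / 4 * e2c
  }
  list(v_between = v_b, v_within = v_w)
}

# rho != 0: full 2-D Gauss-Hermite over the correlated intercepts
overall_decompose_2d <- function(pr, c0, c1, dz, kappa, role_handling, n_nodes) {
  r <- gh_rule(n_nodes)
  k <- length(r$x)
  x1 <- rep(r$x, each = k); x2 <- rep(r$x, times = k)
  w <- rep(r$w, each = k) * rep(r$w, times = k)
  uz <- outer(pr$sigma_z, x1)
  uc <- outer(pr$sigma_c * pr$rho, x1) +
    outer(pr$sigma_c * sqrt(pmax(0, 1 - pr$rho^2)), x2)
  kk <- length(w)
  p0 <- stats::plogis(outer(pr$beta_z0, rep(1, kk)) + uz)
  p1 <- stats::plogis(outer(pr$beta_z0 + dz, rep(1, kk)) + uz)
  m0 <- c0 * exp(uc); m1 <- c1 * exp(uc)
  mu0 <- p0 * m0; mu1m <- p1 * m1
  mubar <- (mu0 + mu1m) / 2
  e1 <- as.numeric(mubar %*% w)
  e2 <- as.numeric(mubar^2 %*% w)
  v_b <- e2 - e1^2
  cv0 <- (1 + kappa) * p0 * m0^2 - mu0^2
  cv1 <- (1 + kappa) * p1 * m1^2 - mu1m^2
  v_w <- as.numeric(((cv0 + cv1) / 2) %*% w)
  if (role_handling == "absolute") {
    v_w <- v_w + as.numeric(((mu0 - mu1m)^2 / 4) %*% w)
  }
  list(v_between = v_b, v_within = v_w)
}

# ---- posterior summaries ------------------------------------------------

icc_summary <- function(values, component, label) {
  q <- stats::quantile(values, c(0.025, 0.5, 0.975), names = FALSE, type = 7)
  structure(list(component = component, label = label,
                 point = q[2], ci_low = q[1], ci_high = q[3],
                 draws = values),
            class = "icc_summary")
}

#' @export
print.icc_summary <- function(x, ...) {
  cat(sprintf("%s [%s]: %.3f, 95%% CI (%.3f, %.3f)%s\n",
              x$component, x$label, x$point, x$ci_low, x$ci_high,
              icc_verbal(x$point, x$component)))
  invisible(x)
}

# conventional verbal anchors, reported as annotation only
icc_verbal <- function(icc, component) {
  if (grepl("difference", component) || is.na(icc) || icc < 0) return("")
  lab <- if (icc < 0.4) "poor" else if (icc < 0.6) "fair"
  else if (icc < 0.75) "good" else "excellent"
  paste0("  [", lab, "]")
}

#' Posterior ICC on the observed data scale
#'
#' Applies the data-scale variance decomposition to every posterior draw
#' and summarizes the resulting ICC by the posterior median and the 95%
#' percentile interval.
#'
#' @param draws a `two_part_draws` object from [fit_two_part()].
#' @param component `"losses"`, `"zero"` or `"overall"`.
#' @param group group label, or `"pooled"` for a pooled fit.
#' @param role_handling see [icc_overall()].
#' @param n_nodes quadrature nodes.
#' @return an `icc_summary` with `point`, `ci_low`, `ci_high` and the
#'   per-draw ICC vector in `$draws`.
#' @export
posterior_icc <- function(draws, component = c("losses", "zero", "overall"),
                          group = NULL,
                          role_handling = c("absolute", "consistency"),
                          n_nodes = 32) {
  component <- match.arg(component)
  role_handling <- match.arg(role_handling)
  if (draws$family == "gaussian") {
    stop("zero/losses/overall components are undefined for the Gaussian model; ",
         "use posterior_gaussian_icc (closed-form gaussian_icc per draw)")
  }
  group <- default_group(draws, group)
  pr <- draw_rows(draws, group)
  dec <- draws_decompose(pr, draws$family, component, role_handling,
                         n_nodes = n_nodes, include_role = draws$include_role)
  icc_summary(icc_of(dec), component, group)
}

#' Posterior ICC of the Gaussian comparison model
#'
#' @param draws a `gaussian_draws` object from [fit_gaussian()].
#' @param group group label, or `"pooled"`.
#' @return an `icc_summary`.
#' @export
posterior_gaussian_icc <- function(draws, group = NULL) {
  if (draws$family != "gaussian") stop("draws are not from a Gaussian fit")
  group <- default_group(draws, group)
  d <- draws$draws
  icc <- gaussian_icc(d[[paste0("sigma_b.", group)]],
                      d[[paste0("sigma_e.", group)]])
  icc_summary(icc, "gaussian", group)
}

#' Posterior difference of two groups' ICCs
#'
#' Per posterior draw, the ICC of `group_a` minus the ICC of `group_b`
#' (for instance partner minus parent), summarized by the posterior
#' median and 95% percentile interval. A positive difference means better
#' agreement in `group_a`.
#'
#' @inheritParams posterior_icc
#' @param group_a,group_b group labels present in the fitted model.
#' @return an `icc_summary` for the difference.
#' @export
icc_difference <- function(draws, component, group_a, group_b,
                           role_handling = c("absolute", "consistency"),
                           n_nodes = 32) {
  role_handling <- match.arg(role_handling)
  for (g in c(group_a, group_b)) {
    if (!g %in% draws$groups) {
      stop(sprintf("group '%s' absent from the fitted model", g))
    }
  }
  if (draws$family == "gaussian") {
    a <- posterior_gaussian_icc(draws, group_a)$draws
    b <- posterior_gaussian_icc(draws, group_b)$draws
  } else {
    a <- posterior_icc(draws, component, group_a, role_handling, n_nodes)$draws
    b <- posterior_icc(draws, component, group_b, role_handling, n_nodes)$draws
  }
  icc_summary(a - b, paste0(component, " difference"),
              paste0(group_a, " - ", group_b))
}

default_group <- function(draws, group) {
  if (is.null(group)) {
    if (length(draws$groups) == 1L) return(draws$groups)
    stop("fit has several groups; specify `group`")
  }
  if (!group %in% draws$groups) {
    stop(sprintf("group '%s' absent from the fitted model", group))
  }
  group
}

# per-draw parameter vectors for one group, in draws_decompose layout
draw_rows <- function(draws, group) {
  d <- draws$draws
  col <- function(stub) d[[paste0(stub, ".", group)]]
  list(beta_z0 = col("beta_z0"), beta_c0 = col("beta_c0"),
       delta_z = d$delta_z, delta_c = d$delta_c,
       sigma_z = col("sigma_z"), sigma_c = col("sigma_c"),
       rho = if (!is.null(col("rho"))) col("rho") else rep(0, nrow(d)),
       shape = if (draws$family == "gamma") col("alpha") else col("s2"))
}

#' Marginal means and zero proportions per rater role
#'
#' For every posterior draw, integrates the fitted model over the random
#' effects to obtain, per role, the marginal mean outcome `E[y]` and the
#' marginal probability of a zero report, averaged across relationship
#' groups with dyad-count weights. Summaries (posterior median, 95%
#' percentile CI) are returned for each role together with the CSO-minus-
#' gambler difference and CSO/gambler ratio of means and the difference of
#' zero proportions.
#'
#' @param draws a `two_part_draws` object.
#' @param n_nodes quadrature nodes.
#' @return data frame with columns `quantity`, `point`, `ci_low`, `ci_high`.
#' @export
role_marginals <- function(draws, n_nodes = 32) {
  if (draws$family == "gaussian") stop("role_marginals requires a two-part fit")
  w <- draws$n_dyads_per_group[draws$groups]
  w <- w / sum(w)
  S <- nrow(draws$draws)
  mean_g <- mean_c <- zero_g <- zero_c <- numeric(S)
  for (i in seq_along(draws$groups)) {
    g <- draws$groups[i]
    pr <- draw_rows(draws, g)
    mm <- marginal_role_moments(pr, draws$family, n_nodes,
                                include_role = draws$include_role)
    mean_g <- mean_g + w[i] * mm$mean0; mean_c <- mean_c + w[i] * mm$mean1
    zero_g <- zero_g + w[i] * mm$zero0; zero_c <- zero_c + w[i] * mm$zero1
  }
  row <- function(q, v) {
    s <- stats::quantile(v, c(.025, .5, .975), names = FALSE)
    data.frame(quantity = q, point = s[2], ci_low = s[1], ci_high = s[3])
  }
  rbind(row("marginal_mean_cso", mean_c),
        row("marginal_mean_gambler", mean_g),
        row("mean_diff_cso_minus_gambler", mean_c - mean_g),
        row("mean_ratio_cso_over_gambler", mean_c / mean_g),
        row("zero_prop_cso", zero_c),
        row("zero_prop_gambler", zero_g),
        row("zero_prop_diff_cso_minus_gambler", zero_c - zero_g))
}

marginal_role_moments <- function(pr, family, n_nodes, include_role = TRUE) {
  dz <- if (include_role) pr$delta_z else 0
  dc <- if (include_role) pr$delta_c else 0
  mean_corr <- if (family == "gamma") 0 else pr$shape / 2
  c0 <- exp(pr$beta_c0 + mean_corr); c1 <- exp(pr$beta_c0 + dc + mean_corr)
  ep0 <- gh_expect(stats::plogis, pr$beta_z0, pr$sigma_z, max(64, n_nodes))
  ep1 <- gh_expect(stats::plogis, pr$beta_z0 + dz, pr$sigma_z, max(64, n_nodes))
  if (all(pr$rho == 0)) {
    e1c <- exp(pr$sigma_c^2 / 2)
    list(mean0 = ep0 * c0 * e1c, mean1 = ep1 * c1 * e1c,
         zero0 = 1 - ep0, zero1 = 1 - ep1)
  } else {
    # E[p(u_z) exp(u_c)] over the correlated bivariate normal: condition on
    # u_z, use the lognormal mean of u_c | u_z, then 1-D quadrature
    cond <- function(eta) {
      f <- function(z) stats::plogis(z)
      r <- gh_rule(max(64, n_nodes))
      k <- length(r$x)
      uz <- outer(pr$sigma_z, r$x)
      p <- stats::plogis(outer(eta, rep(1, k)) + uz)
      shift <- exp(outer(pr$rho * pr$sigma_c / ifelse(pr$sigma_z > 0, pr$sigma_z, 1),
                         rep(1, k)) * uz +
                     outer(pr$sigma_c^2 * (1 - pr$rho^2) / 2, rep(1, k)))
      as.numeric((p * shift) %*% r$w)
    }
    list(mean0 = cond(pr$beta_z0) * c0, mean1 = cond(pr$beta_z0 + dz) * c1,
         zero0 = 1 - ep0, zero1 = 1 - ep1)
  }
}
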