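#' Parameters of the two-part (hurdle) mixed model
#'
#' Container for all parameters of the dyadic two-part GLMM: a logistic
#' model for whether a report is nonzero (the "zero part") and a gamma or
#' lognormal model for the strictly positive amounts (the "losses part"),
#' linked by dyad-level random intercepts that may be correlated. A
#' Gaussian variant holds the parameters of the classical two-level linear
#' mixed model used as a comparison.
#'
#' Per relationship group `g` the two-part linear predictors for a report
#' with random intercepts `(u_z, u_c)` are
#' \deqn{\eta_z = \beta_{z0}[g] + \delta_z \cdot \mathrm{cso} + u_z, \qquad
#'       \eta_c = \beta_{c0}[g] + \delta_c \cdot \mathrm{cso} + u_c,}
#' with `cso = 1` for the concerned significant other and 0 for the
#' gambler (reference). The probability of a nonzero report is
#' `plogis(eta_z)`; the conditional mean of a positive report is
#' `exp(eta_c)` for the gamma family (shape `alpha`, rate `alpha/mean`)
#' and `exp(eta_c + s2/2)` for the lognormal family (log-scale variance
#' `s2`). `(u_z, u_c)` are bivariate normal with standard deviations
#' `sigma_z[g]`, `sigma_c[g]` and correlation `rho[g]`.
#'
#' @param family `"gamma"`, `"lognormal"` or `"gaussian"`.
#' @param groups character vector of group labels (e.g. `c("partner",
#'   "parent", "other")`); all per-group vectors are recycled to and named
#'   by it.
#' @param beta_z0 hurdle intercepts per group (logit scale).
#' @param beta_c0 positive-part intercepts per group (log scale).
#' @param delta_z,delta_c rater-role effects (CSO minus gambler) on the
#'   hurdle (logit) and positive (log) parts; shared across groups.
#' @param sigma_z,sigma_c per-group SDs of the dyad random intercepts of
#'   the two parts (must be `>= 0`).
#' @param rho per-group correlation of the two random intercepts in
#'   `[-1, 1]`; 0 gives the independent variant.
#' @param alpha per-group gamma shape (`> 0`); gamma family only.
#' @param s2 per-group lognormal log-scale variance (`> 0`); lognormal
#'   family only.
#' @param mu,sigma_b,sigma_e Gaussian family only: per-group mean,
#'   between-dyad SD and residual SD.
#'
#' @return An object of class `two_part_params` (a validated list).
#' @examples
#' two_part_params(
#'   family = "gamma", groups = c("partner", "parent"),
#'   beta_z0 = c(2.8, 3.2), beta_c0 = c(6.5, 6.3),
#'   delta_z = -0.6, delta_c = 0,
#'   sigma_z = c(1.0, 0.8), sigma_c = c(1.18, 0.73), rho = 0, alpha = 2
#' )
#' @export
two_part_params <- function(family = c("gamma", "lognormal", "gaussian"),
                            groups = "pooled",
                            beta_z0 = 0, beta_c0 = 0,
                            delta_z = 0, delta_c = 0,
                            sigma_z = 0, sigma_c = 0, rho = 0,
                            alpha = 1, s2 = 1,
                            mu = 0, sigma_b = 1, sigma_e = 1) {
  family <- match.arg(family)
  groups <- as.character(groups)
  if (anyDuplicated(groups)) stop("duplicated group labels")
  per_group <- function(x, nm) {
    if (length(x) == 1L) x <- rep(x, length(groups))
    if (length(x) != length(groups)) {
      stop(sprintf("'%s' must have length 1 or %d", nm, length(groups)))
    }
    stats::setNames(as.numeric(x), groups)
  }
  p <- structure(list(family = family, groups = groups), class = "two_part_params")
  if (family == "gaussian") {
    p$mu <- per_group(mu, "mu")
    p$delta <- as.numeric(delta_c)
    p$sigma_b <- per_group(sigma_b, "sigma_b")
    p$sigma_e <- per_group(sigma_e, "sigma_e")
  } else {
    p$beta_z0 <- per_group(beta_z0, "beta_z0")
    p$beta_c0 <- per_group(beta_c0, "beta_c0")
    p$delta_z <- as.numeric(delta_z)
    p$delta_c <- as.numeric(delta_c)
    p$sigma_z <- per_group(sigma_z, "sigma_z")
    p$sigma_c <- per_group(sigma_c, "sigma_c")
    p$rho <- per_group(rho, "rho")
    if (family == "gamma") p$alpha <- per_group(alpha, "alpha")
    if (family == "lognormal") p$s2 <- per_group(s2, "s2")
  }
  validate_two_part_params(p)
  p
}

validate_two_part_params <- function(p) {
  stopifnot(inherits(p, "two_part_params"))
  if (p$family == "gaussian") {
    if (any(p$sigma_b <= 0) || any(p$sigma_e <= 0)) {
      stop("sigma_b and sigma_e must be positive")
    }
    return(invisible(p))
  }
  if (any(p$sigma_z < 0) || any(p$sigma_c < 0)) {
    stop("random-intercept SDs must be non-negative")
  }
  if (any(abs(p$rho) > 1)) stop("|rho| must not exceed 1")
  if (p$family == "gamma" && any(p$alpha <= 0)) stop("gamma shape must be positive")
  if (p$family == "lognormal" && any(p$s2 <= 0)) stop("lognormal s2 must be positive")
  # 2x2 random-effect covariance must be PSD; guaranteed by |rho| <= 1 and
  # non-negative SDs, but check explicitly for safety
  for (g in p$groups) {
    S <- re_cov(p, g)
    if (min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) < -1e-12) {
      stop("random-effect covariance not positive semidefinite for group ", g)
    }
  }
  invisible(p)
}

re_cov <- function(p, group) {
  sz <- p$sigma_z[[group]]
  sc <- p$sigma_c[[group]]
  r <- p$rho[[group]]
  matrix(c(sz^2, r * sz * sc, r * sz * sc, sc^2), 2, 2)
}

check_group_role <- function(p, group, role) {
  if (!group %in% p$groups) {
    stop(sprintf("unknown group '%s' (model groups: %s)", group,
                 paste(p$groups, collapse = ", ")))
  }
  if (!role %in% c("gambler", "cso")) {
    stop(sprintf("unknown role '%s' (must be 'gambler' or 'cso')", role))
  }
  invisible(TRUE)
}

#' Linear predictors of the two-part model
#'
#' Evaluates the logit-scale (zero part) and log-scale (positive part)
#' linear predictors for one report, given the dyad's random intercepts.
#' The gambler is the reference role; the CSO effect is added for
#' `role = "cso"`.
#'
#' @param params a [two_part_params] object (gamma or lognormal family).
#' @param group group label present in `params$groups`.
#' @param role `"gambler"` or `"cso"`.
#' @param u_z,u_c dyad random intercepts of the zero and positive parts.
#' @return named numeric vector `c(eta_z, eta_c)`.
#' @export
linear_predictors <- function(params, group, role, u_z = 0, u_c = 0) {
  validate_two_part_params(params)
  if (params$family == "gaussian") {
    stop("linear_predictors is defined for the two-part families only")
  }
  check_group_role(params, group, role)
  cso <- as.numeric(role == "cso")
  c(eta_z = unname(params$beta_z0[[group]] + cso * params$delta_z + u_z),
    eta_c = unname(params$beta_c0[[group]] + cso * params$delta_c + u_c))
}

#' Conditional moments of the hurdle outcome
#'
#' Mean and variance of the semicontinuous outcome `y` given the
#' probability `p` of a nonzero report and the conditional mean `m` of the
#' positive part. For the gamma family with shape `alpha`,
#' `E[w^2] = m^2 (1 + 1/alpha)`; for the lognormal family parameterized by
#' its conditional mean `m` and log-scale variance `s2`,
#' `E[w^2] = m^2 exp(s2)`. Then `E[y] = p m` and
#' `Var[y] = p E[w^2] - (p m)^2`.
#'
#' @param p probability of a nonzero report, in `[0, 1]`.
#' @param m conditional mean of the positive part (`> 0`).
#' @param alpha gamma shape (`> 0`); used when `family = "gamma"`.
#' @param s2 lognormal log-scale variance; used when `family = "lognormal"`.
#' @param family `"gamma"` or `"lognormal"`.
#' @return list with `p`, `m`, `mean_y` and `var_y`.
#' @examples
#' conditional_moments(p = 0.5, m = 2, alpha = 2) # mean 1, variance 2
#' @export
conditional_moments <- function(p, m, alpha = NULL, s2 = NULL,
                                family = c("gamma", "lognormal")) {
  family <- match.arg(family)
  if (any(p < 0 | p > 1)) stop("p must lie in [0, 1]")
  if (any(m <= 0)) stop("m must be positive")
  if (family == "gamma") {
    if (is.null(alpha) || any(alpha <= 0)) stop("gamma shape must be positive")
    ew2 <- m^2 * (1 + 1 / alpha)
  } else {
    if (is.null(s2) || any(s2 <= 0)) stop("lognormal s2 must be positive")
    ew2 <- m^2 * exp(s2)
  }
  mean_y <- p * m
  var_y <- p * ew2 - mean_y^2
  list(p = p, m = m, mean_y = mean_y, var_y = var_y)
}

#' Hurdle log density
#'
#' Log density of one observation under the two-part model, conditional on
#' the dyad random intercepts: an atom `1 - p` at zero and, for `y > 0`,
#' `p` times a gamma density with mean `exp(eta_c)` and shape `alpha`
#' (rate `alpha / mean`) or a lognormal density with log-location `eta_c`
#' and log-scale variance `s2`.
#'
#' @inheritParams linear_predictors
#' @param y observed outcome, `>= 0`.
#' @return the log density (finite for `y > 0`).
#' @export
log_density <- function(y, params, group, role, u_z = 0, u_c = 0) {
  if (any(y < 0)) stop("y must be non-negative")
  eta <- linear_predictors(params, group, role, u_z, u_c)
  hurdle_logdens(y, eta_z = eta[["eta_z"]], eta_c = eta[["eta_c"]],
                 family = params$family,
                 shape = switch(params$family,
                                gamma = params$alpha[[group]],
                                lognormal = params$s2[[group]]))
}

# vectorized over y; shape is alpha (gamma) or s2 (lognormal)
hurdle_logdens <- function(y, eta_z, eta_c, family, shape) {
  lp1 <- stats::plogis(eta_z, log.p = TRUE)            # log p
  lp0 <- stats::plogis(eta_z, log.p = TRUE, lower.tail = FALSE) # log(1 - p)
  out <- numeric(length(y))
  zero <- y == 0
  out[zero] <- lp0
  if (any(!zero)) {
    yp <- y[!zero]
    if (family == "gamma") {
      out[!zero] <- lp1 +
        stats::dgamma(yp, shape = shape, rate = shape / exp(eta_c), log = TRUE)
    } else {
      out[!zero] <- lp1 +
        stats::dlnorm(yp, meanlog = eta_c, sdlog = sqrt(shape), log = TRUE)
    }
  }
  out
}

#' ICC of the Gaussian linear mixed model
#'
#' Classical two-level intraclass correlation
#' `sigma_b^2 / (sigma_b^2 + sigma_e^2)`.
#'
#' @param sigma_b between-dyad SD (`> 0`).
#' @param sigma_e residual (within-dyad) SD (`> 0`).
#' @return proportion in `(0, 1)`.
#' @examples
#' gaussian_icc(sqrt(3), 1) # 0.75
#' @export
gaussian_icc <- function(sigma_b, sigma_e) {
  if (any(sigma_b <= 0) || any(sigma_e <= 0)) {
    stop("sigma_b and sigma_e must be positive")
  }
  sigma_b^2 / (sigma_b^2 + sigma_e^2)
}

#' @export
print.two_part_params <- function(x, ...) {
  cat("Two-part model parameters (family:", x$family, ")\n")
  cat("Groups:", paste(x$groups, collapse = ", "), "\n")
  if (x$family == "gaussian") {
    tab <- rbind(mu = x$mu, sigma_b = x$sigma_b, sigma_e = x$sigma_e)
  } else {
    tab <- rbind(beta_z0 = x$beta_z0, beta_c0 = x$beta_c0,
                 sigma_z = x$sigma_z, sigma_c = x$sigma_c, rho = x$rho,
                 if (x$family == "gamma") rbind(alpha = x$alpha)
                 else rbind(s2 = x$s2))
    cat(sprintf("Role effects (CSO - gambler): delta_z = %.3f, delta_c = %.3f\n",
                x$delta_z, x$delta_c))
  }
  print(round(tab, 4))
  invisible(x)
}
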