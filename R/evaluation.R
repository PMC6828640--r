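#' Posterior predictive check
#'
#' Draws `n_rep` replicated datasets from the fitted model (new random
#' effects and outcomes for every replicate, each generated from one
#' posterior draw) with the same dyad/group/role structure as `data`, and
#' compares a fixed set of discrepancy summaries against the observed
#' data: the zero fraction, median, 90th and 99th percentiles, and the
#' maximum. These target the failure modes that matter for skewed
#' semicontinuous reports (mass at zero and the right tail). For a
#' Gaussian fit the fraction of non-positive replicated values is
#' reported as the zero fraction, and the fraction of strictly negative
#' predictions is recorded separately.
#'
#' @param draws a `dyadicc_draws` object.
#' @param data the observed [dyad_data] the model was fitted to.
#' @param n_rep number of replicated datasets (`<=` number of posterior
#'   draws); 0 returns an empty result.
#' @param seed RNG seed for the replication noise.
#' @return object of class `ppc_result`: `$replicated` (one row of
#'   summaries per replicate), `$observed`, and `$p_upper`, the tail
#'   probability `P(T_rep >= T_obs)` per summary.
#' @export
posterior_predictive <- function(draws, data, n_rep = 200, seed = 1) {
  stopifnot(inherits(data, "dyad_data"))
  S <- nrow(draws$draws)
  if (n_rep > S) stop("n_rep exceeds the number of posterior draws (", S, ")")
  summaries <- c("zero_frac", "median", "q90", "q99", "max")
  obs <- ppc_summaries(data$y)
  if (n_rep == 0) {
    return(structure(list(replicated = as.data.frame(matrix(numeric(0), 0, 5,
                            dimnames = list(NULL, summaries))),
                          observed = obs, p_upper = NULL, frac_negative = NULL),
                     class = "ppc_result"))
  }
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  pick <- round(seq(1, S, length.out = n_rep))
  rep_rows <- matrix(NA_real_, n_rep, length(summaries),
                     dimnames = list(NULL, summaries))
  fneg <- numeric(n_rep)
  for (r in seq_len(n_rep)) {
    yrep <- simulate_from_draw(draws, data, pick[r])
    fneg[r] <- mean(yrep < 0)
    if (draws$family == "gaussian") {
      rep_rows[r, ] <- ppc_summaries(yrep, zero_le = TRUE)
    } else {
      rep_rows[r, ] <- ppc_summaries(yrep)
    }
  }
  p_upper <- vapply(summaries, function(s) mean(rep_rows[, s] >= obs[[s]]), 0)
  structure(list(replicated = as.data.frame(rep_rows), observed = obs,
                 p_upper = p_upper, frac_negative = mean(fneg)),
            class = "ppc_result")
}

ppc_summaries <- function(y, zero_le = FALSE) {
  c(zero_frac = if (zero_le) mean(y <= 0) else mean(y == 0),
    median = stats::median(y),
    q90 = unname(stats::quantile(y, 0.9)),
    q99 = unname(stats::quantile(y, 0.99)),
    max = max(y))
}

#' @export
print.ppc_result <- function(x, ...) {
  cat("Posterior predictive check (", nrow(x$replicated), "replicates )\n")
  if (!is.null(x$p_upper)) {
    tab <- data.frame(observed = unlist(x$observed),
                      rep_median = apply(x$replicated, 2, stats::median),
                      p_upper = x$p_upper)
    print(round(tab, 3))
    if (!is.null(x$frac_negative) && x$frac_negative > 0) {
      cat(sprintf("Mean fraction of negative predictions: %.3f\n",
                  x$frac_negative))
    }
  }
  invisible(x)
}

# simulate one replicated outcome vector from posterior draw s
simulate_from_draw <- function(draws, data, s) {
  d <- draws$draws[s, , drop = FALSE]
  grp <- if (draws$group_specific) data$group else rep("pooled", nrow(data))
  dlev <- unique(data$dyad_id)
  didx <- match(data$dyad_id, dlev)
  gd <- grp[match(dlev, data$dyad_id)]
  cso <- as.numeric(data$role == "cso")
  y <- numeric(nrow(data))
  if (draws$family == "gaussian") {
    b <- numeric(length(dlev))
    for (g in draws$groups) {
      sel <- gd == g
      b[sel] <- stats::rnorm(sum(sel), 0, d[[paste0("sigma_b.", g)]])
    }
    y <- vapply(seq_len(nrow(data)), function(i) d[[paste0("mu.", grp[i])]], 0) +
      d$delta * cso + b[didx] +
      stats::rnorm(nrow(data), 0,
                   vapply(seq_len(nrow(data)),
                          function(i) d[[paste0("sigma_e.", grp[i])]], 0))
    return(y)
  }
  x1 <- stats::rnorm(length(dlev)); x2 <- stats::rnorm(length(dlev))
  uz <- uc <- numeric(length(dlev))
  for (g in draws$groups) {
    sel <- gd == g
    sz <- d[[paste0("sigma_z.", g)]]; sc <- d[[paste0("sigma_c.", g)]]
    r <- d[[paste0("rho.", g)]]
    uz[sel] <- sz * x1[sel]
    uc[sel] <- sc * (r * x1[sel] + sqrt(1 - r^2) * x2[sel])
  }
  eta_z <- vapply(seq_len(nrow(data)),
                  function(i) d[[paste0("beta_z0.", grp[i])]], 0) +
    d$delta_z * cso + uz[didx]
  eta_c <- vapply(seq_len(nrow(data)),
                  function(i) d[[paste0("beta_c0.", grp[i])]], 0) +
    d$delta_c * cso + uc[didx]
  z <- stats::rbinom(nrow(data), 1, stats::plogis(eta_z))
  if (draws$family == "gamma") {
    a <- vapply(seq_len(nrow(data)), function(i) d[[paste0("alpha.", grp[i])]], 0)
    w <- stats::rgamma(nrow(data), shape = a, rate = a / exp(eta_c))
  } else {
    s2 <- vapply(seq_len(nrow(data)), function(i) d[[paste0("s2.", grp[i])]], 0)
    w <- stats::rlnorm(nrow(data), meanlog = eta_c, sdlog = sqrt(s2))
  }
  z * w
}

# ---- k-fold cross-validation -------------------------------------------

#' Deterministic dyad-level fold assignment
#'
#' @param dyad_ids vector of dyad identifiers.
#' @param K number of folds.
#' @param seed seed; the assignment is a deterministic function of
#'   `(seed, sorted dyad ids)`.
#' @return named integer vector mapping each dyad id to a fold.
#' @export
kfold_folds <- function(dyad_ids, K, seed) {
  ids <- sort(unique(as.character(dyad_ids)))
  if (K < 2 || K > length(ids)) stop("K must lie in [2, number of dyads]")
  old <- .Random.seed_save(); on.exit(.Random.seed_restore(old))
  set.seed(seed)
  stats::setNames(sample(rep_len(seq_len(K), length(ids))), ids)
}

#' Compare two models by k-fold cross-validation
#'
#' Folds partition dyads (a dyad's two reports are never split). For
#' every fold both models are refitted on the training dyads and each
#' held-out observation is scored by its log predictive density, with the
#' held-out dyad's random effects integrated out (new-dyad prediction)
#' by Gauss-Hermite quadrature. The comparison is
#' `elpd_diff = sum_i (lpd_a_i - lpd_b_i)` with standard error
#' `sqrt(N * var(pointwise differences))`; a negative `elpd_diff` with
#' model order (a = Gaussian, b = gamma) means the gamma model predicts
#' better.
#'
#' @param data a [dyad_data] object.
#' @param config_a,config_b [fit_config] objects for the two models.
#' @param K number of folds (default 10; `K = number of dyads` gives
#'   leave-one-dyad-out).
#' @param seed seed controlling the fold assignment and refit seeds.
#' @param max_draws posterior draws used per lpd evaluation (thinned
#'   evenly).
#' @return object of class `cv_result` with `elpd_diff`, `se_diff`,
#'   per-model elpd totals, and the pointwise table.
#' @export
kfold_compare <- function(data, config_a, config_b, K = 10, seed = 1,
                          max_draws = 400) {
  stopifnot(inherits(data, "dyad_data"))
  folds <- kfold_folds(data$dyad_id, K, seed)
  obs_fold <- folds[as.character(data$dyad_id)]
  lpd_a <- lpd_b <- rep(NA_real_, nrow(data))
  for (k in sort(unique(folds))) {
    train <- dyad_data(data[obs_fold != k, ],
                       metadata = list(list(filter = "cv-train", removed = 0L)))
    test <- data[obs_fold == k, ]
    for (side in c("a", "b")) {
      cfg <- if (side == "a") config_a else config_b
      cfg$seed <- as.integer(seed * 100L + k)
      fit <- tryCatch(
        suppressWarnings(fit_model(train, cfg)),
        error = function(e) stop("refit failed in fold ", k, ": ",
                                 conditionMessage(e), call. = FALSE))
      lp <- lpd_points(fit, test, max_draws = max_draws)
      if (side == "a") lpd_a[obs_fold == k] <- lp else lpd_b[obs_fold == k] <- lp
    }
  }
  dif <- lpd_a - lpd_b
  structure(list(
    elpd_diff = sum(dif),
    se_diff = sqrt(length(dif) * stats::var(dif)),
    elpd_a = sum(lpd_a), elpd_b = sum(lpd_b),
    label_a = config_label(config_a), label_b = config_label(config_b),
    K = K,
    pointwise = data.frame(dyad_id = data$dyad_id, fold = unname(obs_fold),
                           lpd_a = lpd_a, lpd_b = lpd_b)),
    class = "cv_result")
}

config_label <- function(config) {
  paste0(config$family,
         if (config$family != "gaussian") {
           if (config$correlated) " (corr)" else " (indep)"
         })
}

#' @export
print.cv_result <- function(x, ...) {
  cat(sprintf("%d-fold CV: %s versus %s\n", x$K, x$label_a, x$label_b))
  cat(sprintf("elpd_diff = %.1f (SE %.1f)\n", x$elpd_diff, x$se_diff))
  invisible(x)
}

fit_model <- function(data, config) {
  if (config$family == "gaussian") fit_gaussian(data, config)
  else fit_two_part(data, config)
}

# Marginal (new-dyad) log predictive density of each observation in
# `newdata`, averaged over posterior draws.
lpd_points <- function(draws, newdata, n_nodes = 32, max_draws = 400) {
  S <- nrow(draws$draws)
  pick <- if (S > max_draws) round(seq(1, S, length.out = max_draws)) else seq_len(S)
  d <- draws$draws[pick, , drop = FALSE]
  grp <- if (draws$group_specific) newdata$group else rep("pooled", nrow(newdata))
  cso <- as.numeric(newdata$role == "cso")
  out <- numeric(nrow(newdata))
  r64 <- gh_rule(max(64, n_nodes))
  for (i in seq_len(nrow(newdata))) {
    g <- grp[i]
    if (draws$family == "gaussian") {
      mu <- d[[paste0("mu.", g)]] + d$delta * cso[i]
      sd_tot <- sqrt(d[[paste0("sigma_b.", g)]]^2 + d[[paste0("sigma_e.", g)]]^2)
      out[i] <- log(mean(stats::dnorm(newdata$y[i], mu, sd_tot)))
      next
    }
    eta_z <- d[[paste0("beta_z0.", g)]] + d$delta_z * cso[i]
    sz <- d[[paste0("sigma_z.", g)]]
    if (newdata$y[i] == 0) {
      ep <- gh_expect(stats::plogis, eta_z, sz, max(64, n_nodes))
      out[i] <- log(mean(1 - ep))
      next
    }
    eta_c <- d[[paste0("beta_c0.", g)]] + d$delta_c * cso[i]
    sc <- d[[paste0("sigma_c.", g)]]
    rho <- d[[paste0("rho.", g)]]
    shape <- if (draws$family == "gamma") d[[paste0("alpha.", g)]] else d[[paste0("s2.", g)]]
    dens_pos <- function(etac_grid) {
      if (draws$family == "gamma") {
        stats::dgamma(newdata$y[i], shape = shape, rate = shape / exp(etac_grid))
      } else {
        stats::dlnorm(newdata$y[i], meanlog = etac_grid, sdlog = sqrt(shape))
      }
    }
    if (all(rho == 0)) {
      ep <- gh_expect(stats::plogis, eta_z, sz, max(64, n_nodes))
      k <- length(r64$x)
      fg <- dens_pos(outer(eta_c, rep(1, k)) + outer(sc, r64$x))
      ef <- as.numeric(fg %*% r64$w)
      out[i] <- log(mean(ep * ef))
    } else {
      r2 <- gh_rule(max(32, n_nodes))
      x1 <- rep(r2$x, each = length(r2$x)); x2 <- rep(r2$x, times = length(r2$x))
      w2 <- rep(r2$w, each = length(r2$w)) * rep(r2$w, times = length(r2$w))
      kk <- length(w2)
      uz <- outer(sz, x1)
      uc <- outer(sc * rho, x1) + outer(sc * sqrt(pmax(0, 1 - rho^2)), x2)
      p <- stats::plogis(outer(eta_z, rep(1, kk)) + uz)
      fg <- dens_pos(outer(eta_c, rep(1, kk)) + uc)
      out[i] <- log(mean(as.numeric((p * fg) %*% w2)))
    }
  }
  out
}

# ---- Spearman correlation ----------------------------------------------

#' Spearman correlation between raters, per group
#'
#' Rank correlation (average ranks for ties) between the gambler's and
#' the CSO's reports, per relationship group and overall.
#'
#' @param data a [dyad_data] object.
#' @return data frame with `group`, `n_dyads`, `rho`, `small_n` (fewer
#'   than 3 dyads: the estimate is reported but flagged).
#' @export
spearman_by_group <- function(data) {
  wide <- dyad_wide(data)
  one <- function(label, sub) {
    rho <- if (nrow(sub) >= 2 &&
               stats::sd(sub$y_gambler) > 0 && stats::sd(sub$y_cso) > 0) {
      stats::cor(sub$y_gambler, sub$y_cso, method = "spearman")
    } else NA_real_
    data.frame(group = label, n_dyads = nrow(sub), rho = rho,
               small_n = nrow(sub) < 3)
  }
  rbind(one("overall", wide),
        do.call(rbind, lapply(sort(unique(wide$group)), function(g) {
          one(g, wide[wide$group == g, ])
        })))
}
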