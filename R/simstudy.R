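#' True data-scale ICCs of a scenario
#'
#' Evaluates the data-scale variance decomposition at the scenario's true
#' parameters: per group the losses, zero and overall ICCs (two-part
#' scenarios) or the Gaussian ICC, plus the pairwise group differences of
#' the losses and overall ICCs for the first two groups (partner minus
#' parent in the default presets).
#'
#' @param scenario a [sim_scenario].
#' @param role_handling passed to [icc_overall()].
#' @return named numeric vector of estimands, e.g. `losses.partner`,
#'   `overall.parent`, `losses_diff.partner.parent`.
#' @export
true_icc <- function(scenario, role_handling = "absolute") {
  p <- scenario$true_params
  out <- c()
  if (p$family == "gaussian") {
    for (g in p$groups) {
      out[paste0("overall.", g)] <- gaussian_icc(p$sigma_b[[g]], p$sigma_e[[g]])
    }
    return(out)
  }
  for (g in p$groups) {
    for (comp in c("losses", "zero", "overall")) {
      out[paste0(comp, ".", g)] <-
        icc_overall(p, g, component = comp, role_handling = role_handling)$icc
    }
  }
  if (length(p$groups) >= 2) {
    g1 <- p$groups[1]; g2 <- p$groups[2]
    for (comp in c("losses", "overall")) {
      out[paste0(comp, "_diff.", g1, ".", g2)] <-
        out[paste0(comp, ".", g1)] - out[paste0(comp, ".", g2)]
    }
  }
  out
}

rep_seed <- function(seed, rep) {
  as.integer((as.numeric(seed) %% 65536 * 32749 + rep * 7919) %% 2147483629 + 1)
}

# estimand table for one fitted model: one row per estimand with the
# posterior median and 95% percentile CI
model_estimates <- function(fit, estimands, role_handling = "absolute") {
  rows <- lapply(estimands, function(e) {
    parts <- strsplit(e, ".", fixed = TRUE)[[1]]
    comp <- parts[1]
    s <- if (fit$family == "gaussian") {
      if (grepl("_diff", comp)) {
        icc_difference(fit, comp, parts[2], parts[3])
      } else if (comp == "zero") {
        return(NULL) # the Gaussian model has no zero part
      } else {
        posterior_gaussian_icc(fit, parts[2])
      }
    } else if (grepl("_diff", comp)) {
      icc_difference(fit, sub("_diff", "", comp), parts[2], parts[3],
                     role_handling = role_handling)
    } else {
      posterior_icc(fit, comp, parts[2], role_handling = role_handling)
    }
    data.frame(estimand = e, est = s$point, lo = s$ci_low, hi = s$ci_high)
  })
  do.call(rbind, rows)
}

#' Run a Monte Carlo simulation study
#'
#' The validation harness for the two-part agreement model: per
#' replication, a dataset is drawn from the scenario, every candidate
#' model is fitted, and the posterior median and 95% percentile CI of
#' each estimand are recorded. Aggregated over replications it reports,
#' per (model, estimand): the relative bias of the posterior medians
#' (`100 * (mean estimate - truth) / truth`), the coverage of the 95% CI
#' (fraction of replications whose interval contains the truth), and for
#' difference estimands the power (fraction of replications whose
#' interval excludes 0), each with its Monte Carlo standard error.
#'
#' Models may be [fit_config] objects (fitted with a per-replication
#' derived seed) or functions `function(data)` returning a data frame
#' with columns `estimand`, `est`, `lo`, `hi` — the latter supports
#' verifying the harness arithmetic with stub fitters. Failed fits are
#' recorded and excluded from the aggregates, never silently dropped.
#'
#' @param scenario a [sim_scenario]; its seed is ignored in favour of
#'   per-replication seeds derived from `seed`.
#' @param n_reps number of replications.
#' @param models named list of [fit_config]s and/or stub functions.
#' @param seed study seed; replication `r` uses a seed derived from
#'   `(seed, r)`.
#' @param estimands character vector of estimands (default: all from
#'   [true_icc()]).
#' @param role_handling passed through to the ICC computations.
#' @param progress_file optional CSV path; per-replication rows are
#'   appended as they complete and already-completed replications are
#'   skipped on rerun, making long studies resumable.
#' @param verbose print one line per replication.
#' @return object of class `sim_study_result` with `$per_rep`,
#'   `$summary`, `$truth` and `$n_failed`.
#' @export
run_study <- function(scenario, n_reps, models, seed = 1,
                      estimands = NULL, role_handling = "absolute",
                      progress_file = NULL, verbose = FALSE) {
  stopifnot(n_reps >= 1, length(models) >= 1, !is.null(names(models)))
  truth <- true_icc(scenario, role_handling)
  if (is.null(estimands)) estimands <- names(truth)
  if (!all(estimands %in% names(truth))) {
    stop("unknown estimand(s): ",
         paste(setdiff(estimands, names(truth)), collapse = ", "))
  }
  done <- NULL
  if (!is.null(progress_file) && file.exists(progress_file)) {
    done <- utils::read.csv(progress_file,
                            colClasses = c(estimand = "character",
                                           model = "character",
                                           error = "character"))
    done$error[is.na(done$error)] <- ""
  }
  per_rep <- list()
  if (!is.null(done)) per_rep <- list(done)
  done_keys <- if (!is.null(done)) unique(paste(done$rep, done$model)) else character()

  for (r in seq_len(n_reps)) {
    rs <- rep_seed(seed, r)
    sc_r <- scenario
    sc_r$seed <- rs
    data_r <- NULL
    for (m in names(models)) {
      if (paste(r, m) %in% done_keys) next
      if (is.null(data_r)) data_r <- draw_dyads(sc_r)
      spec <- models[[m]]
      res <- tryCatch({
        est <- if (is.function(spec)) {
          spec(data_r)
        } else {
          cfg <- spec
          cfg$seed <- rs
          fit <- suppressWarnings(fit_model(data_r, cfg))
          cbind(model_estimates(fit, estimands, role_handling),
                converged = fit$converged)
        }
        if (is.null(est$converged)) est$converged <- NA
        est <- est[est$estimand %in% estimands, , drop = FALSE]
        cbind(rep = r, model = m, est, error = "")
      }, error = function(e) {
        data.frame(rep = r, model = m, estimand = NA_character_,
                   est = NA_real_, lo = NA_real_, hi = NA_real_,
                   converged = NA, error = conditionMessage(e))
      })
      per_rep[[length(per_rep) + 1L]] <- res
      if (!is.null(progress_file)) {
        utils::write.table(res, progress_file, sep = ",",
                           col.names = !file.exists(progress_file),
                           row.names = FALSE, append = file.exists(progress_file))
      }
      if (verbose) {
        cat(sprintf("rep %d/%d model %s %s\n", r, n_reps, m,
                    if (nzchar(res$error[1])) "FAILED" else "ok"))
      }
    }
  }
  per_rep <- do.call(rbind, per_rep)
  structure(list(per_rep = per_rep,
                 summary = summarize_study(per_rep, truth),
                 truth = truth,
                 n_failed = sum(nzchar(per_rep$error) & !is.na(per_rep$error))),
            class = "sim_study_result")
}

summarize_study <- function(per_rep, truth) {
  ok <- per_rep[!is.na(per_rep$estimand) & per_rep$error == "", , drop = FALSE]
  if (!nrow(ok)) return(NULL)
  keys <- unique(ok[, c("model", "estimand")])
  rows <- lapply(seq_len(nrow(keys)), function(i) {
    sub <- ok[ok$model == keys$model[i] & ok$estimand == keys$estimand[i], ]
    tr <- truth[[keys$estimand[i]]]
    n <- nrow(sub)
    covered <- sub$lo <= tr & tr <= sub$hi
    excl0 <- sub$lo > 0 | sub$hi < 0
    is_diff <- grepl("_diff", keys$estimand[i])
    data.frame(
      model = keys$model[i], estimand = keys$estimand[i], truth = tr,
      n_replications = n,
      mean_estimate = mean(sub$est),
      relative_bias = 100 * (mean(sub$est) - tr) / tr,
      relative_bias_mcse = 100 * stats::sd(sub$est) / sqrt(n) / abs(tr),
      coverage = mean(covered),
      coverage_mcse = sqrt(mean(covered) * (1 - mean(covered)) / n),
      power = if (is_diff) mean(excl0) else NA_real_,
      power_mcse = if (is_diff) sqrt(mean(excl0) * (1 - mean(excl0)) / n)
                   else NA_real_)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' @export
print.sim_study_result <- function(x, ...) {
  cat("Simulation study:",
      length(unique(x$per_rep$rep)), "replications,",
      x$n_failed, "failed fit(s)\n")
  s <- x$summary
  s[, sapply(s, is.numeric)] <- round(s[, sapply(s, is.numeric)], 3)
  print(s)
  invisible(x)
}
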