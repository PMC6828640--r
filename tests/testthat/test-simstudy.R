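stub_fixed <- function(truth, scale = 1, width = 1e-6, shift = 0) {
  force(truth); force(scale); force(width); force(shift)
  function(data) {
    est <- unname(truth) * scale + shift
    data.frame(estimand = names(truth), est = est,
               lo = est - width, hi = est + width)
  }
}

test_that("true ICCs are consistent with their closed forms", {
  p <- two_part_params("gamma", c("partner", "parent"),
                       beta_z0 = 2, beta_c0 = 6.5, sigma_z = 0.8,
                       sigma_c = sqrt(c(icc_losses_invert(0.65, 3),
                                        icc_losses_invert(0.45, 2))),
                       alpha = c(3, 2))
  sc <- sim_scenario(p, c(partner = 73, parent = 50))
  tr <- true_icc(sc, role_handling = "consistency")
  expect_equal(unname(tr["losses.partner"]), 0.65, tolerance = 1e-10)
  expect_equal(unname(tr["losses.parent"]), 0.45, tolerance = 1e-10)
  expect_equal(unname(tr["losses_diff.partner.parent"]), 0.20, tolerance = 1e-10)
  # no between-dyad variance in the positive part: losses ICC is zero
  p0 <- two_part_params("gamma", "g", beta_z0 = 2, sigma_z = 0.5,
                        sigma_c = 0, alpha = 2)
  expect_equal(unname(true_icc(sim_scenario(p0, c(g = 10)))["losses.g"]), 0)
})

test_that("correlated-scenario truth matches Monte Carlo integration", {
  p <- two_part_params("gamma", "g", beta_z0 = 1.5, beta_c0 = 6,
                       sigma_z = 1, sigma_c = 0.8, rho = 0.6, alpha = 2)
  tr <- true_icc(sim_scenario(p, c(g = 10)))
  oracle <- mc_icc_batched(p, "g", "overall", n = 1e6, seed = 4)
  expect_lt(abs(tr[["overall.g"]] - oracle$icc), 3 * oracle$se + 1e-3)
})

test_that("harness metrics are exact for stub fitters", {
  sc <- small_scenario(n = 5)
  tr <- true_icc(sc)
  # unbiased stub covering the truth: zero bias, full coverage
  res <- run_study(sc, 4, list(oracle = stub_fixed(tr)), seed = 5)
  expect_true(all(abs(res$summary$relative_bias) < 1e-3))
  expect_true(all(res$summary$coverage == 1))
  # inflated stub: exactly +20% relative bias, zero coverage
  res2 <- run_study(sc, 4, list(infl = stub_fixed(tr, scale = 1.2)), seed = 5)
  expect_equal(res2$summary$relative_bias, rep(20, nrow(res2$summary)),
               tolerance = 1e-9)
  expect_true(all(res2$summary$coverage == 0))
  # power: a tight interval away from zero detects the difference
  pw <- res$summary$power[grepl("_diff", res$summary$estimand)]
  expect_true(all(pw == 1))
  # an interval straddling zero never does
  wide <- stub_fixed(tr, width = 10)
  res3 <- run_study(sc, 3, list(w = wide), seed = 5)
  expect_true(all(res3$summary$power[grepl("_diff", res3$summary$estimand)] == 0))
})

test_that("harness aggregates match hand-computed values", {
  sc <- small_scenario(n = 5)
  tr <- true_icc(sc)["losses.partner"]
  # three replications with known estimates around a truth of tr
  vals <- c(tr + 0.10, tr - 0.05, tr + 0.01)
  covering <- c(FALSE, TRUE, TRUE) # chosen interval widths below
  widths <- c(0.04, 0.06, 0.02)
  counter <- new.env(); counter$i <- 0
  stub <- function(data) {
    counter$i <- counter$i + 1
    data.frame(estimand = "losses.partner", est = vals[counter$i],
               lo = vals[counter$i] - widths[counter$i],
               hi = vals[counter$i] + widths[counter$i])
  }
  res <- run_study(sc, 3, list(s = stub), seed = 1,
                   estimands = "losses.partner")
  s <- res$summary
  expect_equal(s$relative_bias, 100 * (mean(vals) - tr) / tr, tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(s$coverage, mean(covering))
  expect_equal(s$coverage_mcse, sqrt(mean(covering) * (1 - mean(covering)) / 3))
})

test_that("failed fits are recorded and excluded, never silently dropped", {
  sc <- small_scenario(n = 5)
  tr <- true_icc(sc)
  counter <- new.env(); counter$i <- 0
  flaky <- function(data) {
    counter$i <- counter$i + 1
    if (counter$i == 2) stop("synthetic failure")
    stub_fixed(tr)(data)
  }
  res <- run_study(sc, 3, list(flaky = flaky), seed = 2)
  expect_equal(res$n_failed, 1)
  expect_equal(unique(res$summary$n_replications), 2)
  expect_match(res$per_rep$error[res$per_rep$rep == 2], "synthetic failure")
})

test_that("studies are reproducible and resumable", {
  sc <- small_scenario(n = 5)
  tr <- true_icc(sc)
  noisy <- function(data) {
    # estimate depends on the replication's data, hence on the derived seed
    jitter <- mean(data$y) / 1e6
    data.frame(estimand = names(tr), est = unname(tr) + jitter,
               lo = unname(tr) - 1, hi = unname(tr) + 1)
  }
  r1 <- run_study(sc, 3, list(m = noisy), seed = 42)
  r2 <- run_study(sc, 3, list(m = noisy), seed = 42)
  expect_equal(r1$per_rep$est, r2$per_rep$est)
  r3 <- run_study(sc, 3, list(m = noisy), seed = 43)
  expect_false(isTRUE(all.equal(r1$per_rep$est, r3$per_rep$est)))

  pf <- withr::local_tempfile(fileext = ".csv")
  r4 <- run_study(sc, 2, list(m = noisy), seed = 42, progress_file = pf)
  expect_true(file.exists(pf))
  # resuming with more replications keeps the completed rows identical
  r5 <- run_study(sc, 3, list(m = noisy), seed = 42, progress_file = pf)
  expect_equal(r5$per_rep$est[seq_len(nrow(r4$per_rep))], r4$per_rep$est)
  expect_equal(sort(r5$per_rep$est), sort(r1$per_rep$est))
})
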